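# Shared-clonotype identification and repertoire similarity measures.

# Collapse by key and return a data.frame(key, count, prop) in deterministic
# order (count desc, key asc).
key_counts <- function(x, key = "nt", strip_alleles = TRUE) {
  cx <- collapse_clonotypes(x, key = key, strip_alleles = strip_alleles)
  data.frame(key = clonotype_key(cx, key, strip_alleles),
             count = cx$read_count,
             prop = cx$proportion,
             stringsAsFactors = FALSE)
}

new_overlap_result <- function(value, method, key, n_shared) {
  structure(list(value = value, method = method, key = key,
                 n_shared = as.integer(n_shared)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("%s overlap (key = %s): %.6g  [%d shared clonotypes]\n",
              x$method, x$key, x$value, x$n_shared))
  invisible(x)
}

#' Shared clonotypes between two repertoires
#'
#' Collapses both repertoires by the identity key and tabulates the key
#' values present in both, with each sample's read count and proportion.
#'
#' @param a,b repertoires.
#' @param key identity key mode (see [clonotype_key()]); default `"nt"`.
#' @param strip_alleles strip allele suffixes in gene keys.
#' @return A data frame of class `"shared_table"`: columns `key`,
#'   `count.<idA>`, `prop.<idA>`, `count.<idB>`, `prop.<idB>`,
#'   `n_samples_present` (always 2 here); one row per shared key, sorted by
#'   total count descending then key ascending.
#' @export
shared_clonotypes <- function(a, b, key = "nt", strip_alleles = TRUE) {
  ids <- repertoire_ids(list(a, b))
  ka <- key_counts(a, key, strip_alleles)
  kb <- key_counts(b, key, strip_alleles)
  shared <- intersect(ka$key, kb$key)
  ia <- match(shared, ka$key)
  ib <- match(shared, kb$key)
  out <- data.frame(key = shared,
                    count_a = ka$count[ia], prop_a = ka$prop[ia],
                    count_b = kb$count[ib], prop_b = kb$prop[ib],
                    n_samples_present = rep(2L, length(shared)),
                    stringsAsFactors = FALSE)
  names(out)[2:5] <- c(paste0("count.", ids[1]), paste0("prop.", ids[1]),
                       paste0("count.", ids[2]), paste0("prop.", ids[2]))
  tot <- out[[2]] + out[[4]]
  out <- out[order(-tot, out$key, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("shared_table", "data.frame")
  attr(out, "key") <- key
  out
}

#' Jaccard index of two repertoires
#'
#' \eqn{J = |A \cap B| / |A \cup B|} over the sets of clonotype keys.
#'
#' @inheritParams shared_clonotypes
#' @return An `overlap_result` with `value` in \[0, 1\] and `n_shared`.
#' @export
jaccard_index <- function(a, b, key = "nt", strip_alleles = TRUE) {
  ka <- unique(clonotype_key(a, key, strip_alleles))
  kb <- unique(clonotype_key(b, key, strip_alleles))
  un <- length(union(ka, kb))
  if (un == 0) stop("both repertoires are empty")
  inter <- length(intersect(ka, kb))
  new_overlap_result(inter / un, "jaccard", key, inter)
}

#' Morisita overlap index of two repertoires
#'
#' Abundance-weighted similarity of the two count vectors after collapsing by
#' key. Two variants:
#' \describe{
#'   \item{`"horn"` (default)}{Morisita-Horn,
#'     \eqn{C_H = 2 \sum p_i q_i / (\sum p_i^2 + \sum q_i^2)} over
#'     proportions; bounded in \[0, 1\], equal to 1 iff the proportion
#'     vectors coincide.}
#'   \item{`"classic"`}{the unbiased Morisita index,
#'     \eqn{C = 2 \sum x_i y_i / ((D_x + D_y) X Y)} with
#'     \eqn{D_x = \sum x_i (x_i - 1) / (X (X - 1))}; can exceed 1 and
#'     requires at least 2 reads per sample.}
#' }
#'
#' @inheritParams shared_clonotypes
#' @param variant `"horn"` (default) or `"classic"`.
#' @return An `overlap_result`.
#' @examples
#' a <- repertoire(data.frame(read_count = c(5, 5), cdr3_nt = c("AAA", "CCC")))
#' morisita_overlap(a, a, variant = "classic")$value  # 1.125
#' morisita_overlap(a, a, variant = "horn")$value     # 1
#' @export
morisita_overlap <- function(a, b, key = "nt", variant = c("horn", "classic"),
                             strip_alleles = TRUE) {
  variant <- match.arg(variant)
  ka <- key_counts(a, key, strip_alleles)
  kb <- key_counts(b, key, strip_alleles)
  keys <- union(ka$key, kb$key)
  x <- stats::setNames(rep(0, length(keys)), keys)
  y <- x
  x[ka$key] <- ka$count
  y[kb$key] <- kb$count
  n_shared <- sum(x > 0 & y > 0)
  if (variant == "horn") {
    p <- x / sum(x)
    q <- y / sum(y)
    denom <- sum(p^2) + sum(q^2)
    if (denom == 0) stop("zero denominator: no concentration in either sample")
    value <- 2 * sum(p * q) / denom
  } else {
    X <- sum(x); Y <- sum(y)
    if (X < 2 || Y < 2) stop("classic Morisita requires >= 2 reads per sample")
    dx <- sum(x * (x - 1)) / (X * (X - 1))
    dy <- sum(y * (y - 1)) / (Y * (Y - 1))
    if (dx + dy == 0) stop("zero denominator: no concentration in either sample")
    value <- 2 * sum(x * y) / ((dx + dy) * X * Y)
  }
  new_overlap_result(value, paste0("morisita_", variant), key, n_shared)
}

#' Top-cross curve: intersection of the k most abundant clonotypes
#'
#' For each step k, intersects the top-k clonotypes of the two repertoires
#' (under the deterministic ordering: count descending, key ascending) and
#' records the number of shared keys. A step exceeding a repertoire's size
#' takes the whole repertoire. With `normalize = TRUE` each value is divided
#' by `min(k, |a|, |b|)`, so identical repertoires score exactly 1 at every
#' step.
#'
#' @inheritParams shared_clonotypes
#' @param steps strictly increasing positive integers.
#' @param normalize divide by `min(k, |a|, |b|)` (default `TRUE`).
#' @return A data frame of class `"top_cross"` with columns `step`, `value`.
#' @export
top_cross <- function(a, b, key = "nt", steps = c(1000, 2000, 5000, 10000),
                      normalize = TRUE, strip_alleles = TRUE) {
  if (length(steps) == 0) stop("steps must be a nonempty integer vector")
  if (any(steps < 1) || any(diff(steps) <= 0)) {
    stop("steps must be strictly increasing and >= 1")
  }
  ka <- key_counts(a, key, strip_alleles)
  kb <- key_counts(b, key, strip_alleles)
  vals <- vapply(steps, function(k) {
    inter <- length(intersect(utils::head(ka$key, k), utils::head(kb$key, k)))
    if (normalize) inter / min(k, nrow(ka), nrow(kb)) else inter
  }, numeric(1))
  structure(data.frame(step = as.integer(steps), value = vals),
            class = c("top_cross", "data.frame"),
            key = key, normalized = normalize)
}

#' @export
plot.top_cross <- function(x, ...) {
  graphics::plot(x$step, x$value, type = "b", xlab = "top-k clonotypes",
                 ylab = if (isTRUE(attr(x, "normalized"))) {
                   "shared fraction"
                 } else "shared count",
                 main = "Top-cross overlap", ...)
  invisible(x)
}

#' Pairwise overlap matrix for a set of repertoires
#'
#' Computes a pairwise similarity matrix under the chosen method. Diagonal
#' entries are the self-overlap: the key-richness for `"shared_count"`, 1 for
#' `"jaccard"` and `"morisita_horn"`, and the classic Morisita self-index for
#' `"morisita"`.
#'
#' @param reps list of at least two repertoires.
#' @param method `"shared_count"` (default), `"jaccard"`, `"morisita_horn"`
#'   or `"morisita"`.
#' @param key identity key mode; heatmap-style shared counts are usually
#'   computed on `"aa"`, top-cross on `"nt"`.
#' @param strip_alleles strip allele suffixes in gene keys.
#' @return Symmetric numeric matrix with sample ids as dimnames.
#' @export
overlap_matrix <- function(reps,
                           method = c("shared_count", "jaccard",
                                      "morisita_horn", "morisita"),
                           key = "aa", strip_alleles = TRUE) {
  method <- match.arg(method)
  if (length(reps) < 2) stop("need at least 2 repertoires")
  ids <- repertoire_ids(reps)
  n <- length(reps)
  pair_value <- function(a, b) {
    switch(method,
      shared_count = nrow(shared_clonotypes(a, b, key, strip_alleles)),
      jaccard = jaccard_index(a, b, key, strip_alleles)$value,
      morisita_horn = morisita_overlap(a, b, key, "horn", strip_alleles)$value,
      morisita = morisita_overlap(a, b, key, "classic", strip_alleles)$value
    )
  }
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq(i, n)) {
      v <- if (i == j) {
        switch(method,
          shared_count = length(unique(clonotype_key(reps[[i]], key,
                                                     strip_alleles))),
          jaccard = 1,
          morisita_horn = 1,
          morisita = morisita_overlap(reps[[i]], reps[[i]], key, "classic",
                                      strip_alleles)$value
        )
      } else {
        pair_value(reps[[i]], reps[[j]])
      }
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  m
}

#' Shared-clonotype repertoire across multiple samples
#'
#' Builds the table of clonotype keys present in at least `min_samples`
#' samples, with each sample's read count and proportion (0 when absent).
#' Rows are sorted by the number of samples sharing the clonotype
#' (descending), then by total read count (descending), then key.
#'
#' @param reps list of repertoires.
#' @param key identity key mode; default `"aa"`.
#' @param min_samples minimal number of samples a clonotype must appear in
#'   (>= 2, and at most `length(reps)`).
#' @param strip_alleles strip allele suffixes in gene keys.
#' @return A data frame of class `"shared_table"` with columns `key`, one
#'   `count.<id>` / `prop.<id>` pair per sample, and `n_samples_present`.
#' @export
shared_repertoire <- function(reps, key = "aa", min_samples = 2,
                              strip_alleles = TRUE) {
  if (min_samples < 2) stop("min_samples must be >= 2")
  if (min_samples > length(reps)) {
    stop("min_samples = ", min_samples, " exceeds the number of repertoires (",
         length(reps), ")")
  }
  ids <- repertoire_ids(reps)
  kcs <- lapply(reps, key_counts, key = key, strip_alleles = strip_alleles)
  all_keys <- sort(unique(unlist(lapply(kcs, `[[`, "key"))))
  out <- data.frame(key = all_keys, stringsAsFactors = FALSE)
  present <- integer(length(all_keys))
  total <- numeric(length(all_keys))
  for (s in seq_along(reps)) {
    idx <- match(all_keys, kcs[[s]]$key)
    cnt <- ifelse(is.na(idx), 0L, kcs[[s]]$count[idx])
    prp <- ifelse(is.na(idx), 0, kcs[[s]]$prop[idx])
    out[[paste0("count.", ids[s])]] <- cnt
    out[[paste0("prop.", ids[s])]] <- prp
    present <- present + (cnt > 0)
    total <- total + cnt
  }
  out$n_samples_present <- present
  out <- out[present >= min_samples, , drop = FALSE]
  total <- total[present >= min_samples]
  o <- order(-out$n_samples_present, -total, out$key, method = "radix")
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("shared_table", "data.frame")
  attr(out, "key") <- key
  out
}

#' @export
print.shared_table <- function(x, ...) {
  cat(sprintf("Shared clonotype table (key = %s): %d clonotypes\n",
              attr(x, "key"), nrow(x)))
  print(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat(sprintf("... and %d more rows\n", nrow(x) - 10))
  invisible(x)
}
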