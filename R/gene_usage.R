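# V/J segment usage distributions and their comparison: Shannon entropy,
# Jensen-Shannon divergence and PCA.

#' V or J gene-segment usage of a repertoire
#'
#' Frequency distribution of V (or J) gene segments: the share of clonotypes
#' (or of reads) assigned to each segment. Gene names are compared after
#' allele stripping. A `namespace` fixes the segment order and zero-fills
#' genes absent from the repertoire; genes observed but missing from an
#' explicit namespace raise an error.
#'
#' @param x a `repertoire`.
#' @param segment `"v"` (default) or `"j"`.
#' @param weighting `"clonotypes"` (default) or `"reads"`.
#' @param namespace optional character vector of gene names fixing the
#'   support; `NULL` derives it from the repertoire.
#' @param normalize divide by the total so frequencies sum to 1
#'   (default `TRUE`); `FALSE` returns raw tallies.
#' @param strip_alleles strip `*NN` allele suffixes (default `TRUE`).
#' @return An object of class `"gene_usage"`: a list with `segment`,
#'   `weighting`, and `freq` (named numeric vector over the namespace).
#' @examples
#' r <- repertoire(data.frame(read_count = c(1, 1, 6, 2),
#'                            cdr3_nt = c("AAA", "CCC", "GGG", "TTT"),
#'                            v_gene = c("TRBV1", "TRBV1", "TRBV2", "TRBV3")))
#' gene_usage(r, "v")$freq                        # 0.50 0.25 0.25
#' gene_usage(r, "v", weighting = "reads")$freq   # 0.2 0.6 0.2
#' @export
gene_usage <- function(x, segment = c("v", "j"),
                       weighting = c("clonotypes", "reads"),
                       namespace = NULL, normalize = TRUE,
                       strip_alleles = TRUE) {
  segment <- match.arg(segment)
  weighting <- match.arg(weighting)
  g <- if (segment == "v") x$v_gene else x$j_gene
  if (strip_alleles) g <- strip_allele(g)
  if (all(g == "")) stop("no ", toupper(segment), " gene names in repertoire")
  w <- if (weighting == "reads") as.numeric(x$read_count) else rep(1, nrow(x))
  agg <- rowsum(w, group = g)
  tallies <- stats::setNames(agg[, 1], rownames(agg))
  if (is.null(namespace)) {
    namespace <- sort(names(tallies))
  } else {
    if (strip_alleles) namespace <- strip_allele(namespace)
    extra <- setdiff(names(tallies), namespace)
    if (length(extra) > 0) {
      stop("gene(s) not in namespace: ", paste(extra, collapse = ", "))
    }
  }
  freq <- stats::setNames(rep(0, length(namespace)), namespace)
  freq[names(tallies)] <- tallies
  if (normalize) freq <- freq / sum(freq)
  structure(list(segment = segment, weighting = weighting, freq = freq),
            class = "gene_usage")
}

#' @export
print.gene_usage <- function(x, ...) {
  cat(sprintf("%s gene usage (%s-weighted), %d segments\n",
              toupper(x$segment), x$weighting, length(x$freq)))
  print(round(x$freq, 4))
  invisible(x)
}

#' @export
plot.gene_usage <- function(x, main = NULL, ...) {
  if (is.null(main)) main <- paste(toupper(x$segment), "gene usage")
  graphics::barplot(x$freq, las = 2, main = main, ylab = "frequency", ...)
  invisible(x)
}

# Accept a gene_usage object or a bare probability vector.
as_prob_vector <- function(p, tol = 1e-6) {
  if (inherits(p, "gene_usage")) p <- p$freq
  if (!is.numeric(p) || any(p < 0)) stop("probabilities must be numeric >= 0")
  if (abs(sum(p) - 1) > tol) {
    stop("distribution is not normalized (sums to ", format(sum(p)), ")")
  }
  p
}

#' Shannon entropy of a gene-usage distribution
#'
#' \eqn{H = -\sum_{p_i > 0} p_i \log p_i}; zero-probability segments
#' contribute nothing.
#'
#' @param p a `gene_usage` object or a normalized probability vector.
#' @param base logarithm base (default `exp(1)`).
#' @return Entropy in the chosen base's units (nats by default).
#' @export
usage_entropy <- function(p, base = exp(1)) {
  if (!is.numeric(base) || base <= 1) stop("log base must be > 1")
  p <- as_prob_vector(p)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

# Align two named distributions on the union of their names, zero-filling.
align_union <- function(p, q) {
  if (is.null(names(p)) || is.null(names(q))) {
    if (length(p) != length(q)) {
      stop("unnamed distributions must have equal length")
    }
    return(list(p = p, q = q))
  }
  ns <- sort(union(names(p), names(q)))
  pa <- stats::setNames(rep(0, length(ns)), ns); pa[names(p)] <- p
  qa <- stats::setNames(rep(0, length(ns)), ns); qa[names(q)] <- q
  list(p = pa, q = qa)
}

#' Jensen-Shannon divergence between gene-usage distributions
#'
#' \eqn{JSD(p, q) = H(\frac{p+q}{2}) - \frac{H(p) + H(q)}{2}}. Symmetric,
#' nonnegative, bounded by `log(2)` in the chosen base; its square root is a
#' metric. Distributions over different gene sets are aligned on the union of
#' names with zero fill before comparison.
#'
#' @param p,q `gene_usage` objects or normalized probability vectors.
#' @param base logarithm base (default `exp(1)`, so the maximum is
#'   `log(2)` ~ 0.693).
#' @return The divergence value.
#' @export
usage_jsd <- function(p, q, base = exp(1)) {
  p <- as_prob_vector(p)
  q <- as_prob_vector(q)
  al <- align_union(p, q)
  m <- (al$p + al$q) / 2
  usage_entropy_raw(m, base) -
    (usage_entropy_raw(al$p, base) + usage_entropy_raw(al$q, base)) / 2
}

usage_entropy_raw <- function(p, base) {
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Pairwise Jensen-Shannon divergence matrix
#'
#' Computes [usage_jsd()] between every pair of repertoires over the union
#' gene namespace. The matrix is symmetric with a zero diagonal.
#'
#' @param reps list of at least two repertoires (optionally named).
#' @param segment,weighting,strip_alleles passed to [gene_usage()].
#' @param base logarithm base.
#' @return Symmetric numeric matrix with sample ids as dimnames.
#' @export
usage_jsd_matrix <- function(reps, segment = "v", weighting = "clonotypes",
                             base = exp(1), strip_alleles = TRUE) {
  if (length(reps) < 2) stop("need at least 2 repertoires")
  usages <- lapply(reps, gene_usage, segment = segment, weighting = weighting,
                   strip_alleles = strip_alleles)
  ids <- repertoire_ids(reps)
  n <- length(reps)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      v <- usage_jsd(usages[[i]], usages[[j]], base = base)
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  m
}

repertoire_ids <- function(reps) {
  ids <- names(reps)
  auto <- vapply(reps, sample_id, character(1))
  if (is.null(ids)) ids <- auto
  ids[is.na(ids) | ids == ""] <- auto[is.na(ids) | ids == ""]
  make.unique(ids)
}

#' PCA of gene-usage profiles across samples
#'
#' Principal component analysis of the samples-by-genes usage matrix
#' (union namespace, mean-centered columns, covariance PCA). The sign of each
#' component is fixed so that its largest-magnitude gene loading is positive,
#' which makes the output deterministic.
#'
#' @param reps list of at least two repertoires.
#' @param segment,weighting,strip_alleles passed to [gene_usage()].
#' @param n_components number of components to return; at most
#'   `min(n_samples, n_genes)`.
#' @return A list of class `"usage_pca"` with `scores` (samples x components),
#'   `loadings` (genes x components), `explained_variance` (fractions,
#'   nonincreasing, summing to at most 1), and `usage` (the input matrix).
#' @export
usage_pca <- function(reps, segment = "v", weighting = "clonotypes",
                      n_components = 2, strip_alleles = TRUE) {
  if (length(reps) < 2) stop("need at least 2 repertoires")
  u <- usage_matrix(reps, segment, weighting, strip_alleles)
  k_max <- min(nrow(u), ncol(u))
  if (n_components > k_max) {
    stop("n_components = ", n_components, " exceeds min(n_samples, n_genes) = ",
         k_max)
  }
  pc <- stats::prcomp(u, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  flip <- vapply(seq_len(k), function(j) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, `*`)
  loadings <- sweep(pc$rotation[, seq_len(k), drop = FALSE], 2, flip, `*`)
  tot <- sum(pc$sdev^2)
  ev <- if (tot > 0) pc$sdev^2 / tot else rep(0, length(pc$sdev))
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = ev[seq_len(k)], usage = u),
            class = "usage_pca")
}

# Samples x genes frequency matrix on the union namespace.
usage_matrix <- function(reps, segment = "v", weighting = "clonotypes",
                         strip_alleles = TRUE) {
  usages <- lapply(reps, gene_usage, segment = segment, weighting = weighting,
                   strip_alleles = strip_alleles)
  ns <- sort(Reduce(union, lapply(usages, function(u) names(u$freq))))
  m <- t(vapply(usages, function(u) {
    f <- stats::setNames(rep(0, length(ns)), ns)
    f[names(u$freq)] <- u$freq
    f
  }, numeric(length(ns))))
  rownames(m) <- repertoire_ids(reps)
  m
}

#' @export
print.usage_pca <- function(x, ...) {
  cat(sprintf("Gene-usage PCA: %d samples, %d genes, %d components\n",
              nrow(x$scores), nrow(x$loadings), ncol(x$scores)))
  cat("Explained variance fractions:",
      paste(sprintf("%.3f", x$explained_variance), collapse = ", "), "\n")
  print(round(x$scores, 4))
  invisible(x)
}

#' @export
plot.usage_pca <- function(x, ...) {
  s <- x$scores
  if (ncol(s) < 2) s <- cbind(s, 0)
  graphics::plot(s[, 1], s[, 2],
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$explained_variance[1]),
                 ylab = sprintf("PC2 (%.1f%%)",
                                100 * ifelse(length(x$explained_variance) > 1,
                                             x$explained_variance[2], 0)),
                 main = "Gene-usage PCA", ...)
  graphics::text(s[, 1], s[, 2], labels = rownames(s), pos = 3, cex = 0.8)
  invisible(x)
}
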