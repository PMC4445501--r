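# Per-repertoire descriptive statistics, CDR3 length distributions and
# in-silico spectratyping.

#' Summary statistics of a repertoire
#'
#' Computes the primary descriptive statistics: distinct nucleotide and
#' amino-acid clonotype counts, total reads, mean clonotype read count,
#' in-frame fraction, clonal count skewness and the proportion of the top
#' clone.
#'
#' Skewness is the sample Pearson moment skewness of the read-count vector,
#' \eqn{g_1 = m_3 / m_2^{3/2}} with central moments \eqn{m_k = \frac{1}{n}\sum
#' (x_i - \bar x)^k}. Read counts are heavy-tailed in expanded repertoires;
#' `log10_counts = TRUE` applies `log10` before taking moments.
#'
#' @param x a nonempty `repertoire`.
#' @param log10_counts compute skewness on `log10(read_count)` instead of raw
#'   counts (default `FALSE`).
#' @return An object of class `"repertoire_summary"`: a list with elements
#'   `sample_id`, `n_clonotypes`, `n_clonotypes_nt`, `n_clonotypes_aa`,
#'   `total_reads`, `mean_count`, `in_frame_fraction`, `count_skewness`,
#'   `top_clone_proportion`.
#' @export
summary_stats <- function(x, log10_counts = FALSE) {
  if (nrow(x) == 0) stop("summary_stats needs a nonempty repertoire")
  counts <- as.numeric(x$read_count)
  v <- if (log10_counts) log10(counts) else counts
  m <- mean(v)
  m2 <- mean((v - m)^2)
  m3 <- mean((v - m)^3)
  skew <- if (m2 > 0) m3 / m2^1.5 else 0
  out <- list(
    sample_id = sample_id(x),
    n_clonotypes = nrow(x),
    n_clonotypes_nt = length(unique(x$cdr3_nt)),
    n_clonotypes_aa = length(unique(x$cdr3_aa)),
    total_reads = total_reads(x),
    mean_count = mean(counts),
    in_frame_fraction = mean(is_in_frame(x)),
    count_skewness = skew,
    top_clone_proportion = max(counts) / sum(counts)
  )
  class(out) <- "repertoire_summary"
  out
}

#' @export
print.repertoire_summary <- function(x, ...) {
  cat(sprintf("Repertoire summary for '%s'\n", x$sample_id))
  cat(sprintf("  clonotypes: %d (nt-distinct %d, aa-distinct %d)\n",
              x$n_clonotypes, x$n_clonotypes_nt, x$n_clonotypes_aa))
  cat(sprintf("  total reads: %d  (mean per clonotype %.2f)\n",
              x$total_reads, x$mean_count))
  cat(sprintf("  in-frame fraction: %.3f\n", x$in_frame_fraction))
  cat(sprintf("  count skewness: %.4f   top clone: %.4f of reads\n",
              x$count_skewness, x$top_clone_proportion))
  invisible(x)
}

#' CDR3 length distribution
#'
#' Tallies CDR3 lengths in nucleotides or amino acids, weighting each
#' clonotype by 1 (`"clonotypes"`) or by its read count (`"reads"`). Bin mass
#' therefore sums to the number of clonotypes or to the total reads.
#'
#' @param x a nonempty `repertoire`.
#' @param unit `"nt"` (default) or `"aa"`.
#' @param weighting `"clonotypes"` (default) or `"reads"`.
#' @return A data frame with columns `length` (increasing) and `mass`.
#' @export
cdr3_length_distribution <- function(x, unit = c("nt", "aa"),
                                     weighting = c("clonotypes", "reads")) {
  unit <- match.arg(unit)
  weighting <- match.arg(weighting)
  if (nrow(x) == 0) stop("empty repertoire")
  len <- if (unit == "nt") nchar(x$cdr3_nt) else nchar(x$cdr3_aa)
  w <- if (weighting == "reads") as.numeric(x$read_count) else rep(1, nrow(x))
  agg <- rowsum(w, group = len)
  out <- data.frame(length = as.integer(rownames(agg)), mass = agg[, 1])
  out[order(out$length), , drop = FALSE]
}

#' Clonal proportion: clonotypes accounting for q% of reads
#'
#' The minimal number of most-abundant clonotypes whose cumulative proportion
#' of reads reaches `q`/100, under the deterministic ordering (count
#' descending, nucleotide key ascending).
#'
#' @param x a `repertoire`.
#' @param q target percentage in (0, 100].
#' @return Integer count of clonotypes.
#' @examples
#' r <- repertoire(data.frame(read_count = c(5, 3, 1, 1),
#'                            cdr3_nt = c("AAA", "CCC", "GGG", "TTT")))
#' clonal_proportion(r, 50)  # 1
#' clonal_proportion(r, 80)  # 2
#' @export
clonal_proportion <- function(x, q) {
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q > 100) {
    stop("q must be a percentage in (0, 100]")
  }
  if (nrow(x) == 0) stop("empty repertoire")
  x <- recompute_proportions(x)
  p <- x$proportion[order_clonotypes(x, "nt")]
  cum <- cumsum(p)
  as.integer(which(cum >= q / 100 - 1e-12)[1])
}

#' In-silico spectratype
#'
#' Cross-tabulates clonotypes by V gene and CDR3 nucleotide length, weighting
#' by clonotype count or reads. The grand total equals the number of
#' clonotypes or the total reads; row/column margins agree with
#' [gene_usage()] counts and [cdr3_length_distribution()].
#'
#' @param x a `repertoire` with V gene names.
#' @param weighting `"reads"` (default) or `"clonotypes"`.
#' @param dense pad missing lengths in `min:max` with zero columns (for
#'   plotting); default `FALSE` keeps only observed lengths.
#' @param strip_alleles strip allele suffixes from V names (default `TRUE`).
#' @return A numeric matrix of class `"spectratype"`; rows = V genes
#'   (sorted), columns = CDR3 nt lengths (increasing), attribute
#'   `"weighting"`.
#' @export
spectratype <- function(x, weighting = c("reads", "clonotypes"),
                        dense = FALSE, strip_alleles = TRUE) {
  weighting <- match.arg(weighting)
  if (nrow(x) == 0) stop("empty repertoire")
  v <- if (strip_alleles) strip_allele(x$v_gene) else x$v_gene
  len <- nchar(x$cdr3_nt)
  w <- if (weighting == "reads") as.numeric(x$read_count) else rep(1, nrow(x))
  genes <- sort(unique(v))
  lens <- sort(unique(len))
  if (dense) lens <- seq(min(lens), max(lens))
  m <- matrix(0, nrow = length(genes), ncol = length(lens),
              dimnames = list(genes, as.character(lens)))
  for (i in seq_len(nrow(x))) {
    m[v[i], as.character(len[i])] <- m[v[i], as.character(len[i])] + w[i]
  }
  attr(m, "weighting") <- weighting
  class(m) <- c("spectratype", class(m))
  m
}

#' @export
print.spectratype <- function(x, ...) {
  cat(sprintf("Spectratype (%s-weighted): %d V genes x %d lengths\n",
              attr(x, "weighting"), nrow(x), ncol(x)))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' @export
plot.spectratype <- function(x, main = "CDR3 spectratype", ...) {
  graphics::barplot(unclass(x), main = main, xlab = "CDR3 length (nt)",
                    ylab = attr(x, "weighting"),
                    col = grDevices::hcl.colors(max(nrow(x), 2), "Spectral"),
                    ...)
  invisible(x)
}
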