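# Repertoire diversity estimation: Hill numbers, Gini, Gini-Simpson, inverse
# Simpson, Chao1, rarefaction.

check_counts <- function(counts) {
  if (length(counts) < 1) stop("need at least one abundance")
  if (any(counts < 1) || any(counts != floor(counts))) {
    stop("abundances must be positive integers")
  }
  as.numeric(counts)
}

#' Per-clonotype abundance vector of a repertoire
#'
#' Collapses by the identity key and extracts the read-count vector, the raw
#' material of the diversity estimators.
#'
#' @param x a `repertoire`.
#' @param key identity key mode; default `"nt"`.
#' @param strip_alleles strip allele suffixes in gene keys.
#' @return Integer vector of per-clonotype read counts (one per key class).
#' @export
abundance_vector <- function(x, key = "nt", strip_alleles = TRUE) {
  collapse_clonotypes(x, key, strip_alleles)$read_count
}

#' Hill diversity (effective number of types)
#'
#' The Hill number of order q:
#' \eqn{{}^qD = (\sum_i p_i^q)^{1/(1-q)}} for \eqn{q \neq 1}, with the
#' continuous limits \eqn{{}^1D = \exp(-\sum p_i \ln p_i)} and
#' \eqn{{}^\infty D = 1 / \max_i p_i} (reciprocal Berger-Parker). Order 0 is
#' richness, order 1 the exponential of Shannon entropy, order 2 the inverse
#' Simpson index. Nonincreasing in q.
#'
#' @param p normalized proportion vector (entries >= 0, summing to 1).
#' @param q diversity order, a single real >= 0 (may be `Inf`).
#' @return The effective number of types.
#' @examples
#' hill_diversity(c(0.75, 0.25), 2)  # 1.6
#' @export
hill_diversity <- function(p, q) {
  if (!is.numeric(q) || length(q) != 1 || is.na(q) || q < 0) {
    stop("q must be a single real >= 0")
  }
  p <- as_prob_vector(p)
  p <- p[p > 0]
  if (is.infinite(q)) return(1 / max(p))
  if (abs(q - 1) < 1e-9) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

#' Diversity profile over a grid of Hill orders
#'
#' @param p normalized proportion vector.
#' @param q vector of orders; default `c(0, 0.5, 1, 2, 4, Inf)`.
#' @return Data frame with columns `q` and `hill`.
#' @export
diversity_profile <- function(p, q = c(0, 0.5, 1, 2, 4, Inf)) {
  data.frame(q = q, hill = vapply(q, function(qi) hill_diversity(p, qi),
                                  numeric(1)))
}

#' Gini coefficient of clonal abundances
#'
#' \eqn{G = \sum_i \sum_j |x_i - x_j| / (2 n \sum_i x_i)}; 0 for perfectly
#' even repertoires, approaching \eqn{(n-1)/n} under total dominance of one
#' clone.
#'
#' @param counts vector of positive integer abundances.
#' @return The coefficient in \[0, (n-1)/n\].
#' @export
gini_coefficient <- function(counts) {
  x <- check_counts(counts)
  n <- length(x)
  # O(n log n): sort-based identity for the pairwise absolute-difference sum
  xs <- sort(x)
  sum_abs <- 2 * sum((2 * seq_len(n) - n - 1) * xs)
  sum_abs / (2 * n * sum(x))
}

#' Gini-Simpson index
#'
#' \eqn{1 - \sum_i p_i^2}: the probability that two reads drawn at random
#' belong to different clonotypes.
#'
#' @param p normalized proportion vector.
#' @return Value in \[0, 1 - 1/S\].
#' @export
gini_simpson <- function(p) {
  p <- as_prob_vector(p)
  1 - sum(p^2)
}

#' Inverse Simpson index
#'
#' \eqn{1 / \sum_i p_i^2}, identical to the Hill number of order 2.
#'
#' @param p normalized proportion vector.
#' @return Value in \[1, S\].
#' @export
inverse_simpson <- function(p) {
  p <- as_prob_vector(p)
  1 / sum(p^2)
}

#' Chao1 richness estimator
#'
#' Nonparametric lower-bound estimate of the total number of clonotypes from
#' the singleton count \eqn{f_1} and doubleton count \eqn{f_2}:
#' classic \eqn{S_{obs} + f_1^2 / (2 f_2)} (undefined when \eqn{f_2 = 0}),
#' bias-corrected \eqn{S_{obs} + f_1 (f_1 - 1) / (2 (f_2 + 1))} (always
#' defined; the default).
#'
#' @param counts vector of positive integer abundances.
#' @param variant `"bias_corrected"` (default) or `"classic"`.
#' @return Estimated richness, always >= observed richness.
#' @examples
#' chao1(c(1, 1, 1, 2, 5), "classic")         # 9.5
#' chao1(c(1, 1, 1, 2, 5), "bias_corrected")  # 6.5
#' @export
chao1 <- function(counts, variant = c("bias_corrected", "classic")) {
  variant <- match.arg(variant)
  x <- check_counts(counts)
  s_obs <- length(x)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (variant == "classic") {
    if (f2 == 0) {
      if (f1 == 0) return(s_obs)
      stop("classic Chao1 is undefined with no doubletons; ",
           "use variant = \"bias_corrected\"")
    }
    s_obs + f1^2 / (2 * f2)
  } else {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  }
}

#' Rarefaction curve: expected richness in subsamples
#'
#' Expected number of distinct clonotypes in a random subsample of m reads
#' drawn without replacement. Exact mode uses the hypergeometric formula
#' \eqn{E[S(m)] = \sum_i (1 - \binom{N - x_i}{m} / \binom{N}{m})} evaluated
#' in log-gamma arithmetic (stable up to millions of reads). Resampled mode
#' draws `n_replicates` multivariate-hypergeometric subsamples and reports
#' the mean and standard deviation of observed richness.
#'
#' @param counts vector of positive integer abundances; `N = sum(counts)`.
#' @param sizes increasing subsample sizes, each in \[1, N\].
#' @param mode `"exact"` (default) or `"resampled"`.
#' @param n_replicates replicates in resampled mode (default 100).
#' @param seed optional RNG seed for resampled mode.
#' @return A data frame of class `"rarefaction_curve"`: columns `m`,
#'   `richness`, and `sd` (NA in exact mode).
#' @examples
#' rarefaction_curve(c(2, 2), sizes = 1)$richness  # 1
#' @export
rarefaction_curve <- function(counts, sizes, mode = c("exact", "resampled"),
                              n_replicates = 100, seed = NULL) {
  mode <- match.arg(mode)
  x <- check_counts(counts)
  N <- sum(x)
  if (length(sizes) == 0) stop("sizes must be nonempty")
  sizes <- as.numeric(sizes)
  if (any(sizes < 1) || any(sizes != floor(sizes))) {
    stop("sizes must be positive integers")
  }
  if (is.unsorted(sizes, strictly = TRUE)) stop("sizes must be increasing")
  if (any(sizes > N)) {
    stop("subsample size exceeds total reads N = ", N)
  }
  if (mode == "exact") {
    rich <- vapply(sizes, function(m) {
      # log C(N - x_i, m) - log C(N, m); C(N - x_i, m) = 0 when m > N - x_i
      lr <- ifelse(m > N - x, -Inf,
                   lchoose(N - x, m) - lchoose(N, m))
      sum(1 - exp(lr))
    }, numeric(1))
    sds <- rep(NA_real_, length(sizes))
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      } else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    # a subsample of m reads without replacement is a multivariate
    # hypergeometric draw over the clonotype labels of the N reads
    type_of <- rep.int(seq_along(x), x)
    reps <- matrix(0, nrow = n_replicates, ncol = length(sizes))
    for (r in seq_len(n_replicates)) {
      for (j in seq_along(sizes)) {
        reps[r, j] <- length(unique(type_of[sample.int(N, sizes[j])]))
      }
    }
    rich <- colMeans(reps)
    sds <- apply(reps, 2, stats::sd)
  }
  structure(data.frame(m = as.integer(sizes), richness = rich, sd = sds),
            class = c("rarefaction_curve", "data.frame"),
            mode = mode, s_obs = length(x), total = N)
}

#' @export
plot.rarefaction_curve <- function(x, ...) {
  graphics::plot(x$m, x$richness, type = "b", xlab = "subsample size (reads)",
                 ylab = "expected richness",
                 main = sprintf("Rarefaction (%s)", attr(x, "mode")), ...)
  invisible(x)
}

#' Diversity measures of a repertoire
#'
#' Convenience wrapper: collapses by key, extracts abundances and evaluates
#' the standard diversity panel.
#'
#' @param x a `repertoire`.
#' @param key identity key mode; default `"nt"`.
#' @param q Hill orders for the profile; default `c(0, 0.5, 1, 2, 4, Inf)`.
#' @param strip_alleles strip allele suffixes in gene keys.
#' @return A list of class `"repertoire_diversity"` with elements
#'   `abundances`, `richness`, `hill` (data frame over `q`), `gini`,
#'   `gini_simpson`, `inverse_simpson`, `chao1` (bias-corrected).
#' @export
repertoire_diversity <- function(x, key = "nt", q = c(0, 0.5, 1, 2, 4, Inf),
                                 strip_alleles = TRUE) {
  counts <- abundance_vector(x, key, strip_alleles)
  p <- counts / sum(counts)
  structure(list(
    sample_id = sample_id(x),
    abundances = counts,
    richness = length(counts),
    hill = diversity_profile(p, q),
    gini = gini_coefficient(counts),
    gini_simpson = gini_simpson(p),
    inverse_simpson = inverse_simpson(p),
    chao1 = chao1(counts)
  ), class = "repertoire_diversity")
}

#' @export
print.repertoire_diversity <- function(x, ...) {
  cat(sprintf("Diversity of '%s': richness %d, Chao1 %.1f\n",
              x$sample_id, x$richness, x$chao1))
  cat(sprintf("  Gini %.4f, Gini-Simpson %.4f, inverse Simpson %.2f\n",
              x$gini, x$gini_simpson, x$inverse_simpson))
  hl <- paste(sprintf("^%sD=%.2f", format(x$hill$q), x$hill$hill),
              collapse = "  ")
  cat(" ", hl, "\n")
  invisible(x)
}
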