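# Fixture builders shared across the suite. Everything is generated in code
# under fixed seeds; no fixture files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small explicit repertoire from parallel vectors.
toy_rep <- function(counts, nt = NULL, aa = NULL, v = "", j = "",
                    id = "toy") {
  n <- length(counts)
  if (is.null(nt)) {
    nt <- vapply(seq_len(n), function(i) {
      paste(rep(c("A", "C", "G", "T")[(i - 1) %% 4 + 1], 3 * i), collapse = "")
    }, character(1))
  }
  if (is.null(aa)) aa <- translate_cdr3(nt)
  repertoire(data.frame(read_count = counts, cdr3_nt = nt, cdr3_aa = aa,
                        v_gene = rep_len(v, n), j_gene = rep_len(j, n),
                        stringsAsFactors = FALSE),
             sample_id = id)
}

# Random repertoire with realistic structure: duplicated CDR3s (so collapsing
# has work to do), a shared V/J gene pool with allele suffixes, geometric-ish
# counts, mixed frames.
random_repertoire <- function(n = 60, seed = 1, id = paste0("R", seed),
                              v_pool = paste0("TRBV", 1:6),
                              j_pool = paste0("TRBJ", 1:4),
                              dup_rate = 0.25) {
  withr::with_seed(seed, {
    n_uniq <- max(2, round(n * (1 - dup_rate)))
    lens <- sample(c(9, 12, 13, 15, 18), n_uniq, replace = TRUE)
    nts <- vapply(lens, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
    idx <- sample(n_uniq, n, replace = TRUE)
    nt <- nts[idx]
    alle <- sample(c("", "*01", "*02"), n, replace = TRUE)
    df <- data.frame(
      read_count = 1 + stats::rgeom(n, 0.3),
      cdr3_nt = nt,
      cdr3_aa = translate_cdr3(nt),
      v_gene = paste0(sample(v_pool, n, replace = TRUE), alle),
      j_gene = sample(j_pool, n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    repertoire(df, sample_id = id)
  })
}

# Brute-force all-windows Hamming oracle for motif matching ('X' wildcard).
motif_oracle <- function(seqs, pattern, max_mismatch) {
  pat <- strsplit(pattern, "")[[1]]
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    n <- length(ch); m <- length(pat)
    if (n < m) return(FALSE)
    for (st in 1:(n - m + 1)) {
      mm <- 0
      for (k in 1:m) {
        if (pat[k] != "X" && ch[st + k - 1] != pat[k]) mm <- mm + 1
      }
      if (mm <= max_mismatch) return(TRUE)
    }
    FALSE
  }, logical(1), USE.NAMES = FALSE)
}

# Uniform random probability vector (for property tests over distributions).
random_prob <- function(k, seed) {
  withr::with_seed(seed, {
    p <- stats::rgamma(k, shape = 1)
    p / sum(p)
  })
}

# Random abundance vector with singletons and doubletons present.
random_counts <- function(k = 20, seed = 1) {
  withr::with_seed(seed, 1 + stats::rpois(k, sample(0:5, k, replace = TRUE)))
}
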