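# Filtering, collapsing and motif search over clonotype tables.

#' In-frame status of clonotypes
#'
#' A CDR3 is in frame when its nucleotide length is divisible by 3 and its
#' amino-acid sequence contains no stop codon (`*`).
#'
#' @param x a `repertoire`.
#' @return Logical vector, one entry per clonotype.
#' @export
is_in_frame <- function(x) {
  nchar(x$cdr3_nt) %% 3 == 0 & !grepl("*", x$cdr3_aa, fixed = TRUE)
}

#' Filter clonotypes
#'
#' Keeps the clonotypes satisfying the conjunction of the given predicates,
#' preserving the original order. Proportions are left untouched unless
#' `renormalize = TRUE` (they then refer to the subrepertoire).
#'
#' @param x a `repertoire`.
#' @param frame `"any"` (default), `"in"` (in-frame only) or `"out"`.
#' @param min_count keep clonotypes with `read_count >= min_count`.
#' @param v_gene,j_gene exact gene-name match (after allele stripping when
#'   `strip_alleles` is on); `NULL` = no constraint. A vector matches any of
#'   its elements.
#' @param aa_pattern CDR3 amino-acid motif passed to [motif_search()]
#'   (wildcard `X`, `max_mismatch` mismatches allowed); `NULL` = none.
#' @param max_mismatch mismatch budget for `aa_pattern` (default 0).
#' @param strip_alleles strip `*NN` allele suffixes before gene comparison
#'   (default `TRUE`).
#' @param renormalize recompute proportions within the filtered set.
#' @return The filtered `repertoire` (possibly empty).
#' @examples
#' r <- repertoire(data.frame(read_count = c(10, 5, 1),
#'                            cdr3_nt = c("TGTGCCAGC", "TGTTTTAAA", "TGTAAA")))
#' nrow(filter_clonotypes(r, min_count = 5))  # 2
#' @export
filter_clonotypes <- function(x, frame = c("any", "in", "out"), min_count = 1,
                              v_gene = NULL, j_gene = NULL, aa_pattern = NULL,
                              max_mismatch = 0, strip_alleles = TRUE,
                              renormalize = FALSE) {
  frame <- match.arg(frame)
  keep <- rep(TRUE, nrow(x))
  if (frame != "any") {
    inf <- is_in_frame(x)
    keep <- keep & if (frame == "in") inf else !inf
  }
  keep <- keep & x$read_count >= min_count
  gene_match <- function(col, targets) {
    g <- if (strip_alleles) strip_allele(col) else col
    t <- if (strip_alleles) strip_allele(targets) else targets
    g %in% t
  }
  if (!is.null(v_gene)) keep <- keep & gene_match(x$v_gene, v_gene)
  if (!is.null(j_gene)) keep <- keep & gene_match(x$j_gene, j_gene)
  if (!is.null(aa_pattern)) {
    keep <- keep & motif_matches(x$cdr3_aa, aa_pattern, max_mismatch)
  }
  out <- x[keep, , drop = FALSE]
  if (renormalize && nrow(out) > 0) out <- recompute_proportions(out)
  out
}

#' Collapse clonotypes by identity key
#'
#' Merges clonotypes that share the same identity key (see [clonotype_key()]):
#' read counts are summed, the first-seen row supplies all non-key fields, and
#' the result is sorted by read count descending with ties broken by key
#' string ascending. Proportions are recomputed.
#'
#' @param x a `repertoire`.
#' @param key key mode (`"nt"`, `"aa"`, `"nt+v"`, `"aa+v"`, `"aa+v+j"`).
#' @param strip_alleles strip allele suffixes in gene keys (default `TRUE`).
#' @return The collapsed `repertoire`.
#' @export
collapse_clonotypes <- function(x, key = "nt", strip_alleles = TRUE) {
  if (nrow(x) == 0) return(x)
  k <- clonotype_key(x, key, strip_alleles)
  first <- !duplicated(k)
  sums <- rowsum(as.numeric(x$read_count), group = k, reorder = FALSE)
  out <- x[first, , drop = FALSE]
  out$read_count <- as.integer(sums[match(k[first], rownames(sums)), 1])
  kk <- k[first]
  out <- out[order(-out$read_count, kk, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  recompute_proportions(out)
}

# Logical vector: does any window of each sequence match the motif with at
# most max_mismatch mismatches? 'X' in the pattern matches any symbol and
# never counts as a mismatch.
motif_matches <- function(seqs, pattern, max_mismatch = 0) {
  if (!is.character(pattern) || length(pattern) != 1 || nchar(pattern) == 0) {
    stop("motif pattern must be a nonempty string")
  }
  if (max_mismatch < 0) stop("max_mismatch must be >= 0")
  pat <- strsplit(toupper(pattern), "")[[1]]
  m <- length(pat)
  fixed_pos <- which(pat != "X")
  res <- logical(length(seqs))
  if (length(fixed_pos) == 0) {           # all-wildcard: any long-enough CDR3
    return(nchar(seqs) >= m)
  }
  # fast path: exact contiguous match when no mismatches are allowed
  if (max_mismatch == 0 && length(fixed_pos) == m) {
    return(grepl(pattern, seqs, fixed = TRUE))
  }
  for (i in seq_along(seqs)) {
    s <- strsplit(seqs[i], "")[[1]]
    n <- length(s)
    if (n < m) next
    for (start in seq_len(n - m + 1)) {
      mm <- sum(s[start + fixed_pos - 1L] != pat[fixed_pos])
      if (mm <= max_mismatch) { res[i] <- TRUE; break }
    }
  }
  res
}

#' Search CDR3 sequences for a motif
#'
#' Keeps the clonotypes whose CDR3 (nucleotide or amino acid) contains at
#' least one window matching the pattern with at most `max_mismatch`
#' mismatches. The pattern symbol `X` is a single-position wildcard and never
#' counts as a mismatch. Row order is preserved. A pattern longer than every
#' CDR3 yields an empty repertoire, not an error.
#'
#' @param x a `repertoire`.
#' @param pattern motif over the sequence alphabet plus `X`.
#' @param on `"aa"` (default) or `"nt"`: which CDR3 sequence to scan.
#' @param max_mismatch maximum number of non-wildcard mismatches (default 0).
#' @return The matching sub-repertoire.
#' @examples
#' r <- repertoire(data.frame(read_count = c(1, 1),
#'                            cdr3_nt = c("TGTGCC", "TGCAGC"),
#'                            cdr3_aa = c("CASSLGF", "CSARDF")))
#' motif_search(r, "CASS")$cdr3_aa       # "CASSLGF"
#' motif_search(r, "CXSS")$cdr3_aa       # "CASSLGF"  (X = wildcard)
#' @export
motif_search <- function(x, pattern, on = c("aa", "nt"), max_mismatch = 0) {
  on <- match.arg(on)
  seqs <- if (on == "aa") x$cdr3_aa else x$cdr3_nt
  x[motif_matches(seqs, pattern, max_mismatch), , drop = FALSE]
}
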