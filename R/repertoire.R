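#' @details
#' A repertoire is an ordered collection of clonotypes: classes of sequencing
#' reads sharing a CDR3 sequence and V/J gene assignment. `clonotools`
#' represents it as a plain `data.frame` carrying one row per clonotype and a
#' `"repertoire"` S3 class, so all the usual subsetting and transformation
#' idioms keep working.
#'
#' @keywords internal
"_PACKAGE"

# Canonical column set of a repertoire data frame. Integer columns use -1 as
# the "undefined" sentinel; gene columns use "".
.rep_columns <- c(
  "read_count", "proportion", "cdr3_nt", "cdr3_aa",
  "v_gene", "d_gene", "j_gene",
  "v_end", "d_start", "d_end", "j_start",
  "vd_insertions", "dj_insertions", "total_insertions"
)

.rep_int_cols <- c(
  "read_count", "v_end", "d_start", "d_end", "j_start",
  "vd_insertions", "dj_insertions", "total_insertions"
)
.rep_chr_cols <- c("cdr3_nt", "cdr3_aa", "v_gene", "d_gene", "j_gene")

#' Construct a clonotype repertoire
#'
#' Builds a `repertoire` object from a data frame of clonotypes. Missing
#' optional columns are filled with undefined sentinels (`-1` for integer
#' junction/insertion fields, `""` for gene names and `cdr3_aa`). Clonotype
#' proportions are recomputed from read counts unless `recompute = FALSE`.
#'
#' @param x data frame with at least `read_count` and `cdr3_nt` columns.
#' @param sample_id sample label attached to the repertoire.
#' @param recompute recompute `proportion` from `read_count` (default `TRUE`).
#' @param validate check clonotype invariants (default `TRUE`).
#'
#' @return A `data.frame` of class `"repertoire"` with columns `read_count`,
#'   `proportion`, `cdr3_nt`, `cdr3_aa`, `v_gene`, `d_gene`, `j_gene`,
#'   junction borders `v_end`, `d_start`, `d_end`, `j_start` (0-based
#'   half-open within `cdr3_nt`; `-1` = undefined) and insertion counts
#'   `vd_insertions`, `dj_insertions`, `total_insertions`.
#'
#' @examples
#' r <- repertoire(data.frame(read_count = c(3, 1),
#'                            cdr3_nt = c("TGTGCC", "TGTTTT")))
#' r$proportion  # 0.75 0.25
#' @export
repertoire <- function(x, sample_id = "sample", recompute = TRUE,
                       validate = TRUE) {
  if (!is.data.frame(x)) stop("`x` must be a data.frame")
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!"read_count" %in% names(x)) stop("column `read_count` is required")
  if (!"cdr3_nt" %in% names(x)) stop("column `cdr3_nt` is required")
  for (col in setdiff(.rep_chr_cols, names(x))) x[[col]] <- ""
  for (col in setdiff(.rep_int_cols, names(x))) x[[col]] <- -1L
  if (!"proportion" %in% names(x)) x$proportion <- NA_real_
  x <- x[, .rep_columns]
  for (col in .rep_int_cols) x[[col]] <- as.integer(x[[col]])
  for (col in .rep_chr_cols) x[[col]] <- toupper(as.character(x[[col]]))
  rownames(x) <- NULL
  class(x) <- c("repertoire", "data.frame")
  attr(x, "sample_id") <- as.character(sample_id)
  if (recompute && nrow(x) > 0) x <- recompute_proportions(x)
  if (validate) validate_repertoire(x)
  x
}

#' @rdname repertoire
#' @param object,... passed through (S3 plumbing).
#' @export
is_repertoire <- function(x) inherits(x, "repertoire")

#' Sample identifier of a repertoire
#' @param x a `repertoire`.
#' @return The sample label as a character scalar.
#' @export
sample_id <- function(x) {
  id <- attr(x, "sample_id")
  if (is.null(id)) "sample" else id
}

#' Total read count of a repertoire
#' @param x a `repertoire`.
#' @return Sum of clonotype read counts.
#' @export
total_reads <- function(x) sum(x$read_count)

#' Recompute clonotype proportions from read counts
#'
#' Sets `proportion[i] = read_count[i] / sum(read_count)`.
#'
#' @param x a `repertoire`.
#' @return The repertoire with proportions summing to 1 (within 1e-9).
#' @export
recompute_proportions <- function(x) {
  stopifnot(is.data.frame(x))
  if (nrow(x) == 0) return(x)
  if (any(x$read_count < 1)) stop("all read counts must be >= 1")
  total <- sum(as.numeric(x$read_count))
  if (total <= 0) stop("total read count is zero")
  x$proportion <- as.numeric(x$read_count) / total
  x
}

# Invariant checks; stops with an informative message on violation.
validate_repertoire <- function(x) {
  if (nrow(x) == 0) return(invisible(x))
  if (any(x$read_count < 1)) stop("clonotype read counts must be >= 1")
  bad <- grepl("[^ACGTN]", x$cdr3_nt)
  if (any(bad)) {
    stop("cdr3_nt contains non-ACGTN characters in row(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  }
  # junction border ordering where all four borders are defined
  def <- x$v_end >= 0 & x$d_start >= 0 & x$d_end >= 0 & x$j_start >= 0
  if (any(def)) {
    y <- x[def, ]
    ok <- y$v_end <= y$d_start & y$d_start <= y$d_end &
      y$d_end <= y$j_start & y$j_start <= nchar(y$cdr3_nt)
    if (!all(ok)) stop("junction borders out of order in row(s) ",
                       paste(utils::head(which(def)[!ok], 5), collapse = ", "))
  }
  ins <- x$vd_insertions >= 0 & x$dj_insertions >= 0 & x$total_insertions >= 0
  if (any(ins)) {
    y <- x[ins, ]
    if (!all(y$total_insertions == y$vd_insertions + y$dj_insertions)) {
      stop("total_insertions != vd_insertions + dj_insertions")
    }
  }
  invisible(x)
}

#' @export
print.repertoire <- function(x, ...) {
  cat(sprintf("Repertoire '%s': %d clonotypes, %d reads\n",
              sample_id(x), nrow(x), total_reads(x)))
  if (nrow(x) > 0) {
    show <- utils::head(as.data.frame(x)[, c("read_count", "proportion",
                                             "cdr3_nt", "cdr3_aa",
                                             "v_gene", "j_gene")], 6)
    print(show, digits = 4)
    if (nrow(x) > 6) cat(sprintf("... and %d more rows\n", nrow(x) - 6))
  }
  invisible(x)
}

#' @export
summary.repertoire <- function(object, ...) summary_stats(object, ...)

# Subsetting keeps the class and sample id.
#' @export
`[.repertoire` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && identical(names(out), .rep_columns)) {
    class(out) <- c("repertoire", "data.frame")
    attr(out, "sample_id") <- sample_id(x)
    rownames(out) <- NULL
  }
  out
}

#' Clonotype identity keys
#'
#' Computes the identity string of every clonotype under one of the five key
#' modes used for "same clonotype" decisions: `"nt"` (CDR3 nucleotide),
#' `"aa"` (CDR3 amino acid), `"nt+v"`, `"aa+v"`, `"aa+v+j"`. Gene names are
#' compared after stripping the allele suffix (`*01` etc.) when
#' `strip_alleles` is on.
#'
#' @param x a `repertoire`.
#' @param key key mode, one of `"nt"`, `"aa"`, `"nt+v"`, `"aa+v"`, `"aa+v+j"`.
#' @param strip_alleles drop `*NN` allele suffixes from gene names
#'   (default `TRUE`).
#' @return Character vector of key values, one per clonotype.
#' @export
clonotype_key <- function(x, key = c("nt", "aa", "nt+v", "aa+v", "aa+v+j"),
                          strip_alleles = TRUE) {
  key <- match.arg(key)
  gene <- function(g) if (strip_alleles) strip_allele(g) else g
  switch(key,
    "nt" = x$cdr3_nt,
    "aa" = x$cdr3_aa,
    "nt+v" = paste(x$cdr3_nt, gene(x$v_gene), sep = "|"),
    "aa+v" = paste(x$cdr3_aa, gene(x$v_gene), sep = "|"),
    "aa+v+j" = paste(x$cdr3_aa, gene(x$v_gene), gene(x$j_gene), sep = "|")
  )
}

#' Strip allele suffixes from gene-segment names
#'
#' `"TRBV9*01"` becomes `"TRBV9"`. Vectorized.
#'
#' @param genes character vector of gene names.
#' @return Gene names without `*NN` allele designations.
#' @export
strip_allele <- function(genes) sub("\\*.*$", "", genes)

# Deterministic clonotype ordering used throughout: read count descending,
# then key string ascending.
order_clonotypes <- function(x, key = "nt", strip_alleles = TRUE) {
  k <- clonotype_key(x, key, strip_alleles)
  order(-x$read_count, k, method = "radix")
}
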