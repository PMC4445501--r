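# Tab-delimited clonotype table I/O with configurable column dialects.

# Built-in dialects. `columns` maps logical fields to header names; `borders`
# names the source border convention:
#   "half_open"   -- positions already 0-based half-open (internal convention)
#   "mitcr"       -- 0-based inclusive last-V/last-D positions; first-D/first-J
#                    0-based inclusive starts (converted on read/write)
.builtin_dialects <- list(
  mitcr = list(
    name = "mitcr",
    borders = "mitcr",
    columns = c(
      read_count = "Read count",
      proportion = "Percentage",
      cdr3_nt = "CDR3 nucleotide sequence",
      cdr3_aa = "CDR3 amino acid sequence",
      v_gene = "V segments",
      d_gene = "D segments",
      j_gene = "J segments",
      v_end = "Last V nucleotide position",
      d_start = "First D nucleotide position",
      d_end = "Last D nucleotide position",
      j_start = "First J nucleotide position",
      vd_insertions = "VD insertions",
      dj_insertions = "DJ insertions",
      total_insertions = "Total insertions"
    )
  ),
  generic = list(
    name = "generic",
    borders = "half_open",
    columns = c(
      read_count = "read_count",
      proportion = "proportion",
      cdr3_nt = "cdr3_nt",
      cdr3_aa = "cdr3_aa",
      v_gene = "v_gene",
      d_gene = "d_gene",
      j_gene = "j_gene",
      v_end = "v_end",
      d_start = "d_start",
      d_end = "d_end",
      j_start = "j_start",
      vd_insertions = "vd_insertions",
      dj_insertions = "dj_insertions",
      total_insertions = "total_insertions"
    )
  )
)

#' Column dialect for clonotype tables
#'
#' A dialect maps the logical clonotype fields to the column headers of a
#' tab-delimited clonotype file and declares the junction-border convention
#' of the source. Two dialects ship with the package:
#'
#' * `"mitcr"` (default): MiTCR-style headers (`"Read count"`,
#'   `"CDR3 nucleotide sequence"`, ..., `"Last V nucleotide position"`).
#'   Border positions are 0-based inclusive and converted to the internal
#'   0-based half-open convention on read.
#' * `"generic"`: internal field names as headers, borders already half-open.
#'
#' A custom dialect is a named list/file with elements `columns` (named
#' character vector `logical_field = "Header"`) and optionally `borders`
#' (`"half_open"` or `"mitcr"`). Only `read_count` and `cdr3_nt` are
#' mandatory; unmapped optional fields are set to undefined sentinels.
#'
#' @param x dialect name (`"mitcr"`, `"generic"`), a list as described above,
#'   or a path to a JSON/YAML file holding one.
#' @return A validated dialect list with elements `name`, `borders`,
#'   `columns`.
#' @examples
#' d <- clonotype_dialect("mitcr")
#' d$columns[["read_count"]]
#' @export
clonotype_dialect <- function(x = "mitcr") {
  if (is.list(x) && !is.null(x$columns)) {
    d <- x
  } else if (is.character(x) && length(x) == 1) {
    if (x %in% names(.builtin_dialects)) {
      return(.builtin_dialects[[x]])
    } else if (file.exists(x)) {
      d <- read_dialect_file(x)
    } else {
      stop("unknown dialect '", x, "' (not a builtin name or existing file)")
    }
  } else {
    stop("dialect must be a name, a file path, or a list with $columns")
  }
  d$columns <- unlist(d$columns)
  if (is.null(d$borders)) d$borders <- "half_open"
  if (!d$borders %in% c("half_open", "mitcr")) {
    stop("unknown border convention '", d$borders, "'")
  }
  if (is.null(d$name)) d$name <- "custom"
  missing <- setdiff(c("read_count", "cdr3_nt"), names(d$columns))
  if (length(missing) > 0) {
    stop("dialect must map required field(s): ", paste(missing, collapse = ", "))
  }
  unknown <- setdiff(names(d$columns), .rep_columns)
  if (length(unknown) > 0) {
    stop("dialect maps unknown field(s): ", paste(unknown, collapse = ", "))
  }
  d
}

read_dialect_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML dialects requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

# Convert source border columns to the internal 0-based half-open convention
# (and back). MiTCR reports 0-based inclusive positions: the half-open end of
# the V (or D) piece is last-position + 1; starts coincide. -1 stays -1.
borders_to_internal <- function(df, convention) {
  if (convention == "half_open") return(df)
  for (col in c("v_end", "d_end")) {
    def <- df[[col]] >= 0
    df[[col]][def] <- df[[col]][def] + 1L
  }
  df
}

borders_to_source <- function(df, convention) {
  if (convention == "half_open") return(df)
  for (col in c("v_end", "d_end")) {
    def <- df[[col]] >= 0
    df[[col]][def] <- df[[col]][def] - 1L
  }
  df
}

#' Read a tab-delimited clonotype table
#'
#' Parses one clonotype per row from a TSV file (UTF-8, tab separator, `.`
#' decimal, no quoting) under a column dialect, preserving row order and
#' recomputing proportions from read counts.
#'
#' @param path file path or connection.
#' @param dialect dialect name, list or file; see [clonotype_dialect()].
#' @param sample_id sample label; defaults to the file base name.
#' @return A [repertoire()].
#' @seealso [write_clonotypes()]
#' @export
read_clonotypes <- function(path, dialect = "mitcr", sample_id = NULL) {
  d <- clonotype_dialect(dialect)
  if (is.null(sample_id)) {
    sample_id <- if (is.character(path)) {
      tools::file_path_sans_ext(basename(path))
    } else "sample"
  }
  raw <- tryCatch(
    utils::read.delim(path, check.names = FALSE, colClasses = "character",
                      quote = "", na.strings = NULL,
                      stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse '", path, "': ",
                             conditionMessage(e))
  )
  if (ncol(raw) == 0) stop("empty clonotype file: no header found")
  for (field in c("read_count", "cdr3_nt")) {
    if (!d$columns[[field]] %in% names(raw)) {
      stop("required column '", d$columns[[field]], "' (", field,
           ") missing from header")
    }
  }
  df <- data.frame(row.names = seq_len(nrow(raw)))
  for (field in intersect(names(d$columns), .rep_columns)) {
    src <- d$columns[[field]]
    if (src %in% names(raw)) df[[field]] <- raw[[src]]
  }
  counts <- suppressWarnings(as.numeric(df$read_count))
  bad <- is.na(counts) | counts != floor(counts)
  if (any(bad)) {
    stop("non-integer read count at data line ", which(bad)[1],
         ": '", df$read_count[which(bad)[1]], "'")
  }
  df$read_count <- as.integer(counts)
  for (col in intersect(setdiff(.rep_int_cols, "read_count"), names(df))) {
    v <- suppressWarnings(as.integer(df[[col]]))
    v[is.na(v)] <- -1L
    df[[col]] <- v
  }
  if ("proportion" %in% names(df)) {
    df$proportion <- suppressWarnings(as.numeric(df$proportion))
  }
  df <- borders_to_internal(df, d$borders)
  if (nrow(df) == 0) stop("empty repertoire: '", path, "' has no data rows")
  repertoire(df, sample_id = sample_id)
}

#' Write a clonotype table
#'
#' Serializes a repertoire as a TSV re-parseable by [read_clonotypes()] under
#' the same dialect. Undefined sentinels (`-1`, empty gene names) are written
#' as-is; border positions are converted back to the dialect's convention.
#'
#' @param x a `repertoire`.
#' @param path output file path or connection.
#' @param dialect dialect name, list or file; see [clonotype_dialect()].
#' @return `path`, invisibly.
#' @export
write_clonotypes <- function(x, path, dialect = "mitcr") {
  stopifnot(is_repertoire(x) || is.data.frame(x))
  d <- clonotype_dialect(dialect)
  df <- as.data.frame(x)
  df <- borders_to_source(df, d$borders)
  fields <- intersect(names(d$columns), names(df))
  out <- df[, fields, drop = FALSE]
  names(out) <- d$columns[fields]
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "")
    TRUE
  }, error = function(e) stop("cannot write '", path, "': ",
                              conditionMessage(e)))
  invisible(path)
}
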