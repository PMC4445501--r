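# Automatic report generation: single-sample and multi-sample analysis
# bundles, markdown/HTML rendering, figure generation with TSV sidecars.

.log_levels <- c(debug = 1, info = 2, warning = 3, error = 4)

ct_log <- function(level, ..., threshold = getOption("clonotools.log_level",
                                                     "info")) {
  if (.log_levels[[level]] >= .log_levels[[threshold]]) {
    message(sprintf("[%s] %s", toupper(level), paste0(...)))
  }
}

#' Analysis configuration for report generation
#'
#' Bundles all knobs of the reporting pipeline. Every field mirrors a CLI
#' flag; a JSON/YAML config file with the same names can be loaded with
#' [read_analysis_config()] (explicit flags win over file values).
#'
#' @param dialect clonotype-table dialect for file inputs.
#' @param key identity key for overlap/shared-clonotype analysis
#'   (default `"aa"`, the usual choice for cross-sample heatmaps).
#' @param top_cross_key identity key for top-cross curves (default `"nt"`).
#' @param weighting `"clonotypes"` or `"reads"` for gene usage.
#' @param spectratype_weighting weighting for the spectratype
#'   (default `"reads"`).
#' @param q Hill orders of the diversity profile.
#' @param top_cross_steps increasing step ladder of the top-cross curves.
#' @param rarefaction_points number of rarefaction grid points per sample.
#' @param min_samples minimal sample count for the shared repertoire table.
#' @param sections which report sections to compute; defaults to all.
#' @param seed RNG seed recorded in the report and used by any stochastic
#'   step.
#' @param timestamps include a generation timestamp in the report header
#'   (default `FALSE`, keeping reruns byte-identical).
#' @param log_level one of `"debug"`, `"info"`, `"warning"`, `"error"`.
#' @return A list of class `"analysis_config"`.
#' @export
analysis_config <- function(dialect = "mitcr", key = "aa",
                            top_cross_key = "nt",
                            weighting = "clonotypes",
                            spectratype_weighting = "reads",
                            q = c(0, 0.5, 1, 2, 4, Inf),
                            top_cross_steps = c(10, 50, 100, 500, 1000),
                            rarefaction_points = 10,
                            min_samples = 2,
                            sections = c("summary", "lengths", "spectratype",
                                         "usage", "diversity", "rarefaction",
                                         "overlap", "jsd", "top_cross",
                                         "shared"),
                            seed = 1, timestamps = FALSE,
                            log_level = "info") {
  stopifnot(all(q >= 0), !is.unsorted(top_cross_steps, strictly = TRUE))
  structure(list(dialect = dialect, key = key, top_cross_key = top_cross_key,
                 weighting = weighting,
                 spectratype_weighting = spectratype_weighting,
                 q = q, top_cross_steps = top_cross_steps,
                 rarefaction_points = rarefaction_points,
                 min_samples = min_samples,
                 sections = sections, seed = seed, timestamps = timestamps,
                 log_level = log_level),
            class = "analysis_config")
}

#' Read an analysis configuration from JSON or YAML
#'
#' @param path config file; field names as in [analysis_config()].
#' @param ... overrides applied after the file is read (flags win).
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path, ...) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML configs require the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  vals <- vals[names(vals) %in% names(formals(analysis_config))]
  if (!is.null(vals$q)) vals$q <- vapply(vals$q, function(x) {
    if (identical(x, "Inf")) Inf else as.numeric(x)
  }, numeric(1))
  do.call(analysis_config, vals)
}

# Load an input that may be a repertoire already or a TSV path.
as_repertoire_input <- function(x, dialect) {
  if (is_repertoire(x)) x else read_clonotypes(x, dialect = dialect)
}

fmt_num <- function(x) {
  vapply(as.numeric(x), function(v) {
    if (is.na(v)) "NA"
    else if (v == floor(v) && abs(v) < 1e15) sprintf("%d", as.integer(v))
    else sprintf("%.6g", v)
  }, character(1))
}

# Deterministic TSV writer for report tables (matrices keep rownames).
write_tsv_table <- function(x, path) {
  if (is.matrix(x)) {
    df <- data.frame(id = rownames(x), as.data.frame(unclass(x),
                                                     check.names = FALSE),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

md_table <- function(df, max_rows = 25) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  shown <- utils::head(df, max_rows)
  lines <- c(
    paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  )
  if (nrow(shown) > 0) {
    cells <- vapply(shown, function(col) {
      if (is.numeric(col)) fmt_num(col) else as.character(col)
    }, character(nrow(shown)))
    if (nrow(shown) == 1) cells <- matrix(cells, nrow = 1)
    lines <- c(lines, apply(cells, 1, function(r) {
      paste0("| ", paste(r, collapse = " | "), " |")
    }))
  }
  if (nrow(df) > max_rows) {
    lines <- c(lines, "", sprintf("*... %d more rows (see TSV)*",
                                  nrow(df) - max_rows))
  }
  lines
}

matrix_as_df <- function(m) {
  data.frame(id = rownames(m), as.data.frame(unclass(m), check.names = FALSE),
             check.names = FALSE, stringsAsFactors = FALSE)
}

summary_as_df <- function(s) {
  data.frame(sample = s$sample_id, n_clonotypes = s$n_clonotypes,
             n_clonotypes_nt = s$n_clonotypes_nt,
             n_clonotypes_aa = s$n_clonotypes_aa,
             total_reads = s$total_reads, mean_count = s$mean_count,
             in_frame_fraction = s$in_frame_fraction,
             count_skewness = s$count_skewness,
             top_clone_proportion = s$top_clone_proportion,
             stringsAsFactors = FALSE)
}

diversity_as_df <- function(d) {
  hill <- d$hill
  out <- data.frame(sample = d$sample_id, measure = c(
    "richness", "chao1", "gini", "gini_simpson", "inverse_simpson",
    paste0("hill_q", format(hill$q, trim = TRUE))),
    value = c(d$richness, d$chao1, d$gini, d$gini_simpson,
              d$inverse_simpson, hill$hill),
    stringsAsFactors = FALSE)
  out
}

# Compute the per-sample tables shared by both report flavours.
single_sample_tables <- function(x, config) {
  tabs <- list()
  sec <- config$sections
  if ("summary" %in% sec) tabs$summary <- summary_as_df(summary_stats(x))
  if ("lengths" %in% sec) {
    ld <- cdr3_length_distribution(x, unit = "nt",
                                   weighting = config$weighting)
    tabs$length_distribution <- ld
  }
  if ("spectratype" %in% sec) {
    tabs$spectratype <- spectratype(x, weighting =
                                      config$spectratype_weighting)
  }
  if ("usage" %in% sec) {
    uv <- gene_usage(x, "v", weighting = config$weighting)
    uj <- tryCatch(gene_usage(x, "j", weighting = config$weighting),
                   error = function(e) NULL)
    tabs$v_usage <- data.frame(gene = names(uv$freq), frequency = uv$freq,
                               row.names = NULL, stringsAsFactors = FALSE)
    if (!is.null(uj)) {
      tabs$j_usage <- data.frame(gene = names(uj$freq), frequency = uj$freq,
                                 row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  if ("diversity" %in% sec) {
    tabs$diversity <- diversity_as_df(
      repertoire_diversity(x, key = "nt", q = config$q))
  }
  if ("rarefaction" %in% sec) {
    counts <- abundance_vector(x, "nt")
    N <- sum(counts)
    sizes <- unique(round(seq(1, N,
                              length.out = min(config$rarefaction_points,
                                               N))))
    rc <- rarefaction_curve(counts, sizes, mode = "exact")
    tabs$rarefaction <- data.frame(sample = sample_id(x),
                                   as.data.frame(rc),
                                   stringsAsFactors = FALSE)
  }
  tabs
}

write_bundle_tables <- function(tables, out_dir) {
  paths <- list()
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_tsv_table(tables[[nm]], p)
    paths[[nm]] <- p
  }
  paths
}

render_markdown <- function(title, header_lines, tables, out_dir) {
  lines <- c(paste("#", title), "", header_lines, "")
  pretty <- c(summary = "Summary statistics",
              length_distribution = "CDR3 length distribution",
              spectratype = "Spectratype",
              v_usage = "V gene usage", j_usage = "J gene usage",
              diversity = "Diversity", rarefaction = "Rarefaction",
              overlap = "Shared-clonotype counts",
              jaccard = "Jaccard indices",
              morisita_horn = "Morisita-Horn indices",
              jsd = "Jensen-Shannon divergence of V usage",
              top_cross = "Top-cross curves",
              shared = "Shared clonotype repertoire")
  for (nm in names(tables)) {
    ttl <- if (nm %in% names(pretty)) pretty[[nm]] else nm
    lines <- c(lines, paste("##", ttl), "")
    tab <- tables[[nm]]
    df <- if (is.matrix(tab)) matrix_as_df(tab) else as.data.frame(tab)
    lines <- c(lines, md_table(df), "",
               sprintf("Data: [`%s.tsv`](%s.tsv)", nm, nm), "")
  }
  md_path <- file.path(out_dir, "report.md")
  writeLines(lines, md_path)
  html_path <- file.path(out_dir, "report.html")
  writeLines(md_to_html(lines, title), html_path)
  list(markdown = md_path, html = html_path)
}

# Minimal markdown -> HTML rendering for the report subset (headers, pipe
# tables, emphasis, links); intentionally not a general converter.
md_to_html <- function(lines, title) {
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  inline <- function(s) {
    s <- gsub("\\[`?([^]`]+)`?\\]\\(([^)]+)\\)", "<a href='\\2'>\\1</a>", s)
    s <- gsub("\\*\\*([^*]+)\\*\\*", "<b>\\1</b>", s)
    gsub("\\*([^*]+)\\*", "<i>\\1</i>", s)
  }
  out <- c("<!DOCTYPE html>", "<html><head><meta charset='utf-8'>",
           paste0("<title>", esc(title), "</title>"),
           "<style>body{font-family:sans-serif;margin:2em}table{border-collapse:collapse}td,th{border:1px solid #999;padding:2px 8px}</style>",
           "</head><body>")
  in_table <- FALSE
  for (ln in lines) {
    if (grepl("^\\|", ln)) {
      if (grepl("^\\|[-| ]+\\|$", ln)) next
      cells <- strsplit(sub("\\|\\s*$", "", sub("^\\|\\s*", "", ln)),
                        "\\s*\\|\\s*")[[1]]
      tag <- if (!in_table) "th" else "td"
      if (!in_table) { out <- c(out, "<table>"); in_table <- TRUE }
      out <- c(out, paste0("<tr>", paste0("<", tag, ">", inline(esc(cells)),
                                          "</", tag, ">", collapse = ""),
                           "</tr>"))
    } else {
      if (in_table) { out <- c(out, "</table>"); in_table <- FALSE }
      if (grepl("^## ", ln)) {
        out <- c(out, paste0("<h2>", inline(esc(sub("^## ", "", ln))),
                             "</h2>"))
      } else if (grepl("^# ", ln)) {
        out <- c(out, paste0("<h1>", inline(esc(sub("^# ", "", ln))),
                             "</h1>"))
      } else if (nzchar(ln)) {
        out <- c(out, paste0("<p>", inline(esc(ln)), "</p>"))
      }
    }
  }
  if (in_table) out <- c(out, "</table>")
  c(out, "</body></html>")
}

report_header <- function(config, n_samples) {
  lines <- c(sprintf("Samples: %d. Seed: %d. Key: %s. Weighting: %s.",
                     n_samples, config$seed, config$key, config$weighting))
  if (isTRUE(config$timestamps)) {
    lines <- c(lines, sprintf("Generated: %s.", format(Sys.time())))
  }
  lines
}

#' Single-sample analysis report
#'
#' Runs the full single-repertoire pipeline — summary statistics, CDR3
#' length distribution, spectratype, V/J gene usage, diversity profile and
#' exact rarefaction — writes every table as TSV plus a markdown and HTML
#' report into `out_dir`, and returns the bundle. Deterministic given
#' `config$seed`; reruns are byte-identical when `config$timestamps` is off.
#'
#' @param x a `repertoire` or a clonotype TSV path.
#' @param out_dir output directory (created if missing).
#' @param config an [analysis_config()].
#' @return A list of class `"report_bundle"`: `tables` (named list),
#'   `table_paths`, `report` (markdown/html paths), `config`, `sample_ids`.
#' @export
run_single_report <- function(x, out_dir, config = analysis_config()) {
  old_opt <- options(clonotools.log_level = config$log_level)
  on.exit(options(old_opt))
  x <- as_repertoire_input(x, config$dialect)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ct_log("info", "single-sample report for '", sample_id(x), "' (",
         nrow(x), " clonotypes)")
  set.seed(config$seed)
  tables <- single_sample_tables(x, config)
  paths <- write_bundle_tables(tables, out_dir)
  report <- render_markdown(
    paste("Repertoire report:", sample_id(x)),
    report_header(config, 1), tables, out_dir)
  structure(list(tables = tables, table_paths = paths, report = report,
                 config = config, sample_ids = sample_id(x)),
            class = "report_bundle")
}

#' Multi-sample analysis report
#'
#' Runs the group pipeline on two or more repertoires: per-sample summary
#' and diversity tables, gene-usage matrix, pairwise Jensen-Shannon
#' divergence, shared-clonotype count / Jaccard / Morisita-Horn matrices,
#' top-cross curves for every pair, the shared-clonotype repertoire table
#' and per-sample exact rarefaction. All tables are written as TSV plus a
#' markdown/HTML report.
#'
#' @param inputs list of repertoires or clonotype TSV paths (>= 2).
#' @param out_dir output directory.
#' @param config an [analysis_config()].
#' @return A `"report_bundle"` (see [run_single_report()]).
#' @export
run_group_report <- function(inputs, out_dir, config = analysis_config()) {
  old_opt <- options(clonotools.log_level = config$log_level)
  on.exit(options(old_opt))
  if (length(inputs) < 2) stop("group report needs at least 2 samples")
  reps <- lapply(inputs, as_repertoire_input, dialect = config$dialect)
  ids <- repertoire_ids(reps)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ct_log("info", "group report for ", length(reps), " samples")
  set.seed(config$seed)
  sec <- config$sections
  tables <- list()
  if ("summary" %in% sec) {
    tables$summary <- do.call(rbind, lapply(reps, function(r) {
      summary_as_df(summary_stats(r))
    }))
  }
  if ("usage" %in% sec) {
    um <- usage_matrix(reps, "v", config$weighting)
    tables$v_usage <- um
  }
  if ("jsd" %in% sec) {
    tables$jsd <- usage_jsd_matrix(reps, "v", config$weighting)
  }
  if ("overlap" %in% sec) {
    tables$overlap <- overlap_matrix(reps, "shared_count", config$key)
    tables$jaccard <- overlap_matrix(reps, "jaccard", config$key)
    tables$morisita_horn <- overlap_matrix(reps, "morisita_horn", config$key)
  }
  if ("top_cross" %in% sec) {
    curves <- list()
    for (i in seq_along(reps)[-length(reps)]) {
      for (j in seq(i + 1, length(reps))) {
        tc <- top_cross(reps[[i]], reps[[j]], key = config$top_cross_key,
                        steps = config$top_cross_steps)
        curves[[length(curves) + 1]] <- data.frame(
          pair = paste(ids[i], ids[j], sep = ":"), as.data.frame(tc),
          stringsAsFactors = FALSE)
      }
    }
    tables$top_cross <- do.call(rbind, curves)
  }
  if ("shared" %in% sec) {
    tables$shared <- as.data.frame(
      shared_repertoire(reps, key = config$key,
                        min_samples = min(config$min_samples, length(reps))))
  }
  if ("diversity" %in% sec) {
    tables$diversity <- do.call(rbind, lapply(reps, function(r) {
      diversity_as_df(repertoire_diversity(r, key = "nt", q = config$q))
    }))
  }
  if ("rarefaction" %in% sec) {
    tables$rarefaction <- do.call(rbind, lapply(reps, function(r) {
      counts <- abundance_vector(r, "nt")
      N <- sum(counts)
      sizes <- unique(round(seq(1, N,
                                length.out = min(config$rarefaction_points,
                                                 N))))
      data.frame(sample = sample_id(r),
                 as.data.frame(rarefaction_curve(counts, sizes, "exact")),
                 stringsAsFactors = FALSE)
    }))
  }
  paths <- write_bundle_tables(tables, out_dir)
  report <- render_markdown(
    paste("Group repertoire report:", paste(ids, collapse = ", ")),
    report_header(config, length(reps)), tables, out_dir)
  structure(list(tables = tables, table_paths = paths, report = report,
                 config = config, sample_ids = ids),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("Report bundle: %d table(s) for sample(s) %s\n",
              length(x$tables), paste(x$sample_ids, collapse = ", ")))
  cat("Tables:", paste(names(x$tables), collapse = ", "), "\n")
  cat("Report:", x$report$markdown, "\n")
  invisible(x)
}

#' Render the figures of a report bundle
#'
#' Draws one figure per available panel — shared-clonotype heatmap, V-usage
#' bars, JSD one-vs-rest radar table rendered as bars, spectratype stacked
#' bars, rarefaction curves and top-cross lines — in each requested format.
#' Every figure gets a TSV sidecar holding exactly the plotted numbers
#' (figures are views of tables, never computations).
#'
#' @param bundle a `"report_bundle"`.
#' @param formats subset of `"png"`, `"svg"` (empty = no files, success).
#' @param out_dir output directory; defaults to the bundle's report
#'   directory.
#' @return Character vector of written image paths, invisibly.
#' @export
render_plots <- function(bundle, formats = "png", out_dir = NULL) {
  supported <- c("png", "svg")
  bad <- setdiff(formats, supported)
  if (length(bad) > 0) {
    stop("unsupported format(s): ", paste(bad, collapse = ", "),
         " (supported: ", paste(supported, collapse = ", "), ")")
  }
  if (is.null(out_dir)) out_dir <- dirname(bundle$report$markdown)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  panels <- list(
    overlap = function() {
      m <- as_matrix_table(bundle$tables$overlap)
      heatmap_panel(m, "Shared clonotypes")
    },
    jsd = function() {
      m <- as_matrix_table(bundle$tables$jsd)
      heatmap_panel(m, "Jensen-Shannon divergence")
    },
    v_usage = function() usage_panel(bundle$tables$v_usage),
    spectratype = function() {
      plot.spectratype(bundle$tables$spectratype)
    },
    rarefaction = function() rarefaction_panel(bundle$tables$rarefaction),
    top_cross = function() top_cross_panel(bundle$tables$top_cross)
  )
  for (nm in names(panels)) {
    if (is.null(bundle$tables[[nm]])) next
    sidecar <- file.path(out_dir, paste0("figure_", nm, ".tsv"))
    write_tsv_table(bundle$tables[[nm]], sidecar)
    for (fmt in formats) {
      img <- file.path(out_dir, paste0("figure_", nm, ".", fmt))
      if (fmt == "png") {
        grDevices::png(img, width = 900, height = 600)
      } else {
        grDevices::svg(img, width = 9, height = 6)
      }
      ok <- tryCatch({ panels[[nm]](); TRUE },
                     error = function(e) {
                       ct_log("warning", "panel ", nm, " failed: ",
                              conditionMessage(e))
                       FALSE
                     })
      grDevices::dev.off()
      if (ok) written <- c(written, img) else unlink(img)
    }
  }
  invisible(written)
}

as_matrix_table <- function(x) {
  if (is.matrix(x)) return(x)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[1]]
  m
}

heatmap_panel <- function(m, title) {
  n <- nrow(m)
  graphics::image(seq_len(n), seq_len(n), t(m[n:1, , drop = FALSE]),
                  axes = FALSE, xlab = "", ylab = "", main = title,
                  col = grDevices::hcl.colors(25, "YlOrRd", rev = TRUE))
  graphics::axis(1, at = seq_len(n), labels = colnames(m), las = 2)
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(m)), las = 2)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    graphics::text(j, n - i + 1, fmt_num(m[i, j]), cex = 0.8)
  }
}

usage_panel <- function(u) {
  if (is.matrix(u)) {
    graphics::barplot(u, beside = TRUE, las = 2, main = "V gene usage",
                      ylab = "frequency", legend.text = rownames(u))
  } else {
    graphics::barplot(stats::setNames(u$frequency, u$gene), las = 2,
                      main = "V gene usage", ylab = "frequency")
  }
}

rarefaction_panel <- function(tab) {
  samples <- unique(tab$sample)
  cols <- grDevices::hcl.colors(max(length(samples), 2), "Dark 3")
  graphics::plot(range(tab$m), range(tab$richness), type = "n",
                 xlab = "reads subsampled", ylab = "expected richness",
                 main = "Rarefaction")
  for (k in seq_along(samples)) {
    s <- tab[tab$sample == samples[k], ]
    graphics::lines(s$m, s$richness, col = cols[k], lwd = 2)
  }
  graphics::legend("bottomright", legend = samples, col =
                     cols[seq_along(samples)], lwd = 2, cex = 0.8)
}

top_cross_panel <- function(tab) {
  pairs <- unique(tab$pair)
  cols <- grDevices::hcl.colors(max(length(pairs), 2), "Dark 3")
  graphics::plot(range(tab$step), range(tab$value), type = "n",
                 xlab = "top-k clonotypes", ylab = "normalized shared",
                 main = "Top-cross overlap")
  for (k in seq_along(pairs)) {
    s <- tab[tab$pair == pairs[k], ]
    graphics::lines(s$step, s$value, col = cols[k], lwd = 2, type = "b")
  }
  graphics::legend("topright", legend = pairs, col = cols[seq_along(pairs)],
                   lwd = 2, cex = 0.8)
}
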