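# Report generation, determinism, figure sidecars, and the CLI front end.

sim_samples <- function(n = 3, draws = 400) {
  m <- default_model()
  lapply(seq_len(n), function(i) {
    generate_repertoire(m, draws, seed = 100 + i, sample_id = paste0("S", i),
                        expansion = 1.2)
  })
}

dir_digest <- function(d) {
  files <- sort(list.files(d, recursive = TRUE, full.names = TRUE))
  vapply(files, function(f) paste(tools::md5sum(f)), character(1))
}

test_that("single-sample report contains exactly the configured sections", {
  r <- sim_samples(1)[[1]]
  cfg <- analysis_config(sections = c("summary", "diversity"),
                         log_level = "error")
  out <- withr::local_tempdir()
  b <- run_single_report(r, out, cfg)
  expect_named(b$tables, c("summary", "diversity"))
  expect_true(file.exists(file.path(out, "summary.tsv")))
  expect_true(file.exists(file.path(out, "report.md")))
  expect_true(file.exists(file.path(out, "report.html")))
  expect_false(file.exists(file.path(out, "spectratype.tsv")))
})

test_that("single-sample report tables equal direct module calls", {
  r <- sim_samples(1)[[1]]
  out <- withr::local_tempdir()
  b <- run_single_report(r, out, analysis_config(log_level = "error"))
  d <- repertoire_diversity(r, key = "nt")
  got <- b$tables$diversity
  expect_equal(got$value[got$measure == "gini"], d$gini)
  expect_equal(got$value[got$measure == "chao1"], d$chao1)
  expect_equal(got$value[got$measure == "richness"], d$richness)
  expect_equal(b$tables$summary$count_skewness,
               summary_stats(r)$count_skewness)
  expect_equal(as.matrix(unclass(b$tables$spectratype)),
               as.matrix(unclass(spectratype(r, "reads"))),
               ignore_attr = TRUE)
})

test_that("reports are byte-identical across reruns with the same seed", {
  reps <- sim_samples(3)
  cfg <- analysis_config(top_cross_steps = c(5, 20, 50),
                         log_level = "error")
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  run_group_report(reps, out1, cfg)
  run_group_report(reps, out2, cfg)
  h1 <- dir_digest(out1)
  h2 <- dir_digest(out2)
  expect_equal(unname(h1), unname(h2))
  expect_equal(basename(names(h1)), basename(names(h2)))
})

test_that("group report matrices equal the module outputs", {
  reps <- sim_samples(3)
  cfg <- analysis_config(top_cross_steps = c(5, 20, 50),
                         log_level = "error")
  out <- withr::local_tempdir()
  b <- run_group_report(reps, out, cfg)
  expect_equal(b$tables$jsd, usage_jsd_matrix(reps, "v", "clonotypes"))
  expect_equal(b$tables$overlap, overlap_matrix(reps, "shared_count", "aa"))
  expect_equal(b$tables$morisita_horn,
               overlap_matrix(reps, "morisita_horn", "aa"))
  tc <- top_cross(reps[[1]], reps[[2]], key = "nt", steps = c(5, 20, 50))
  sub <- b$tables$top_cross[b$tables$top_cross$pair == "S1:S2", ]
  expect_equal(sub$value, tc$value)
  shared <- shared_repertoire(reps, key = "aa", min_samples = 2)
  expect_equal(b$tables$shared$key, shared$key)
})

test_that("two identical samples give zero JSD and richness off-diagonal", {
  r <- sim_samples(1)[[1]]
  r2 <- r
  attr(r2, "sample_id") <- "S2"
  out <- withr::local_tempdir()
  b <- run_group_report(list(r, r2), out,
                        analysis_config(top_cross_steps = c(5, 20),
                                        log_level = "error"))
  expect_equal(b$tables$jsd["S1", "S2"], 0, tolerance = 1e-12)
  rich <- length(unique(clonotype_key(r, "aa")))
  expect_equal(b$tables$overlap["S1", "S2"], rich)
})

test_that("permuting input order permutes tables consistently", {
  reps <- sim_samples(3)
  cfg <- analysis_config(top_cross_steps = c(5, 20), log_level = "error")
  b1 <- run_group_report(reps, withr::local_tempdir(), cfg)
  b2 <- run_group_report(reps[c(3, 1, 2)], withr::local_tempdir(), cfg)
  ids <- rownames(b1$tables$jsd)
  expect_equal(b2$tables$jsd[ids, ids], b1$tables$jsd)
  expect_equal(b2$tables$overlap[ids, ids], b1$tables$overlap)
  # shared repertoire has the same rows, with per-sample columns re-homed
  expect_setequal(b2$tables$shared$key, b1$tables$shared$key)
})

test_that("figures are optional, validated, and carry exact TSV sidecars", {
  reps <- sim_samples(2)
  out <- withr::local_tempdir()
  b <- run_group_report(reps, out,
                        analysis_config(top_cross_steps = c(5, 20),
                                        log_level = "error"))
  expect_length(render_plots(b, formats = character(0)), 0)
  expect_error(render_plots(b, formats = "gif"), "unsupported")
  figdir <- withr::local_tempdir()
  imgs <- render_plots(b, formats = "png", out_dir = figdir)
  expect_true(length(imgs) >= 3)
  expect_true(all(file.exists(imgs)))
  # sidecar round-trip: the plotted jsd matrix equals the bundle table
  side <- utils::read.delim(file.path(figdir, "figure_jsd.tsv"),
                            check.names = FALSE)
  m <- as.matrix(side[, -1])
  rownames(m) <- side[[1]]
  expect_equal(m, b$tables$jsd, tolerance = 1e-12)
})

test_that("config files load with flag overrides winning", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(key = "nt", seed = 5, weighting = "reads"),
                       f, auto_unbox = TRUE)
  cfg <- read_analysis_config(f)
  expect_equal(cfg$key, "nt")
  expect_equal(cfg$seed, 5)
  cfg2 <- read_analysis_config(f, key = "aa")
  expect_equal(cfg2$key, "aa")
  expect_equal(cfg2$weighting, "reads")
})

test_that("the CLI runs end to end with documented exit codes", {
  skip_if_not_installed("optparse")
  cli <- file.path(find.package("clonotools"), "exec", "clonotools")
  skip_if_not(file.exists(cli), "installed CLI script not found")
  rscript <- file.path(R.home("bin"), "Rscript")
  env <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  run_cli <- function(...) {
    suppressWarnings(system2(rscript, c(cli, ...), stdout = TRUE,
                             stderr = TRUE, env = env))
  }
  status <- function(x) attr(x, "status") %||% 0L
  # usage error: no subcommand
  expect_equal(status(run_cli()), 1L)
  # data error: nonexistent input
  expect_equal(status(run_cli("stats", "/nonexistent.tsv")), 2L)
  # happy path: simulate then stats
  out <- withr::local_tempdir()
  r1 <- run_cli("simulate", "--n-sequences", "200", "--seed", "3",
                "--out-dir", out, "--dialect", "generic")
  expect_equal(status(r1), 0L)
  expect_true(file.exists(file.path(out, "simulated.tsv")))
  r2 <- run_cli("stats", "--dialect", "generic", "--out-dir", out,
                file.path(out, "simulated.tsv"))
  expect_equal(status(r2), 0L)
  stats <- utils::read.delim(file.path(out, "stats.tsv"))
  expect_equal(stats$total_reads, 200L)
})
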