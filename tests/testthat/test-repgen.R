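# The V(D)J generative simulator and CDR3 translation.

degenerate_model <- function() {
  one <- function(x) matrix(1, nrow = 1, ncol = 1)
  generative_model(
    v_segments = c(V1 = "TGTGCC"),
    d_segments = c(D1 = "AGCAGC"),
    j_segments = c(J1 = "TTTGGG"),
    p_v = 1, p_dj = matrix(1, 1, 1),
    p_del_v = one(), p_del_j = one(), p_del_d5 = one(), p_del_d3 = one(),
    p_ins_len_vd = 1, p_ins_len_dj = 1,
    ins_markov_vd = list(initial = rep(0.25, 4),
                         transition = matrix(0.25, 4, 4)),
    ins_markov_dj = list(initial = rep(0.25, 4),
                         transition = matrix(0.25, 4, 4))
  )
}

test_that("translation follows the standard code with junction conventions", {
  expect_equal(translate_cdr3("TGTGCCAGCTTT"), "CASF")
  expect_equal(translate_cdr3("TGA"), "*")
  expect_equal(translate_cdr3("TGTGC"), "C~")
  expect_equal(translate_cdr3("TGTANC"), "C?")
  expect_equal(translate_cdr3(""), "")
  expect_error(translate_cdr3("TGU"), "invalid nucleotide")
  expect_equal(translate_cdr3(c("TTT", "ATGG")), c("F", "M~"))
})

test_that("translation of complete codons agrees with Biostrings", {
  skip_if_not_installed("Biostrings")
  withr::with_seed(31, {
    seqs <- vapply(1:40, function(i) {
      paste(sample(c("A", "C", "G", "T"), 3 * sample(2:8, 1),
                   replace = TRUE), collapse = "")
    }, character(1))
  })
  want <- as.character(Biostrings::translate(Biostrings::DNAStringSet(seqs),
                                             no.init.codon = TRUE))
  expect_equal(translate_cdr3(seqs), unname(want))
})

test_that("the degenerate model is fully deterministic", {
  m <- degenerate_model()
  r <- generate_repertoire(m, 50, seed = 1)
  expect_equal(nrow(r), 1)
  expect_equal(r$read_count, 50L)
  expect_equal(r$cdr3_nt, "TGTGCCAGCAGCTTTGGG")  # V + D + J, no trimming
  expect_equal(r$v_end, 6L)
  expect_equal(r$d_start, 6L)
  expect_equal(r$d_end, 12L)
  expect_equal(r$j_start, 12L)
  expect_equal(r$total_insertions, 0L)
  em <- empirical_marginals(generation_records(r), m)
  expect_equal(unname(em$v), 1)
  expect_equal(as.numeric(em$dj), 1)
  expect_equal(em$ins_len_vd[1], 1)
})

test_that("generation is seed-deterministic", {
  m <- default_model()
  r1 <- generate_repertoire(m, 500, seed = 11)
  r2 <- generate_repertoire(m, 500, seed = 11)
  expect_identical(r1, r2)
  r3 <- generate_repertoire(m, 500, seed = 12)
  expect_false(identical(r1$cdr3_nt, r3$cdr3_nt))
  expect_error(generate_repertoire(m, 10), "seed")
})

test_that("every record reassembles to its CDR3 with consistent borders", {
  m <- default_model()
  r <- generate_repertoire(m, 400, seed = 5)
  rec <- generation_records(r)
  expect_equal(sum(rec$count), 400)  # conservation of draws
  trim_v <- substr(m$v_segments[rec$v_name], 1,
                   nchar(m$v_segments[rec$v_name]) - rec$del_v)
  trim_d <- substr(m$d_segments[rec$d_name], rec$del_d5 + 1,
                   nchar(m$d_segments[rec$d_name]) - rec$del_d3)
  trim_j <- substr(m$j_segments[rec$j_name], rec$del_j + 1,
                   nchar(m$j_segments[rec$j_name]))
  expect_equal(paste0(trim_v, rec$ins_vd, trim_d, rec$ins_dj, trim_j),
               rec$cdr3_nt, ignore_attr = TRUE)
  # borders index the assembled pieces
  expect_equal(rec$v_end, nchar(trim_v), ignore_attr = TRUE)
  expect_equal(rec$d_start, rec$v_end + nchar(rec$ins_vd))
  expect_equal(rec$d_end, rec$d_start + nchar(trim_d), ignore_attr = TRUE)
  expect_equal(rec$j_start, rec$d_end + nchar(rec$ins_dj))
  expect_equal(rec$j_start + nchar(trim_j), nchar(rec$cdr3_nt),
               ignore_attr = TRUE)
  # the repertoire rows are the collapsed records
  expect_equal(total_reads(r), 400)
  expect_setequal(r$cdr3_nt, unique(rec$cdr3_nt))
})

test_that("empirical marginals converge to the model on a doubling ladder", {
  m <- default_model()
  tv <- function(a, b) 0.5 * sum(abs(a - b))
  tvs <- vapply(c(1000, 10000), function(n) {
    em <- empirical_marginals(
      generation_records(generate_repertoire(m, n, seed = 99)), m)
    tv(em$ins_len_vd, m$p_ins_len_vd)
  }, numeric(1))
  expect_lt(tvs[2], tvs[1])
  # frequency tables conserve record mass
  em <- empirical_marginals(
    generation_records(generate_repertoire(m, 2000, seed = 4)), m)
  expect_equal(sum(em$v), 1, tolerance = 1e-9)
  expect_equal(sum(em$dj), 1, tolerance = 1e-9)
  expect_equal(sum(em$ins_len_dj), 1, tolerance = 1e-9)
})

test_that("model validation rejects malformed parameters", {
  m <- default_model()
  expect_error(generative_model(
    v_segments = c(V1 = "TGTGCC"), d_segments = c(D1 = "AAA"),
    j_segments = c(J1 = "TTT"),
    p_v = 0.5, p_dj = matrix(1, 1, 1),
    p_del_v = matrix(1, 1, 1), p_del_j = matrix(1, 1, 1),
    p_del_d5 = matrix(1, 1, 1), p_del_d3 = matrix(1, 1, 1),
    p_ins_len_vd = 1, p_ins_len_dj = 1,
    ins_markov_vd = m$ins_markov_vd, ins_markov_dj = m$ins_markov_dj
  ), "p_v")
  # deletion distribution with no feasible support for a short segment
  expect_error(generative_model(
    v_segments = c(V1 = "TG"), d_segments = c(D1 = "AAA"),
    j_segments = c(J1 = "TTT"),
    p_v = 1, p_dj = matrix(1, 1, 1),
    p_del_v = matrix(c(0, 0, 0, 0, 1), 1, 5),  # always delete 4 nt
    p_del_j = matrix(1, 1, 1),
    p_del_d5 = matrix(1, 1, 1), p_del_d3 = matrix(1, 1, 1),
    p_ins_len_vd = 1, p_ins_len_dj = 1,
    ins_markov_vd = m$ins_markov_vd, ins_markov_dj = m$ins_markov_dj
  ), "feasible")
  expect_error(generate_repertoire(m, 0, seed = 1), "n_sequences")
})

test_that("models round-trip through JSON", {
  m <- default_model()
  f <- withr::local_tempfile(fileext = ".json")
  write_generative_model(m, f)
  m2 <- read_generative_model(f)
  expect_equal(m2$v_segments, m$v_segments)
  expect_equal(m2$p_v, m$p_v, tolerance = 1e-12)
  expect_equal(m2$p_dj, m$p_dj, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(m2$ins_markov_vd$transition, m$ins_markov_vd$transition,
               tolerance = 1e-12, ignore_attr = TRUE)
  # generation from the reloaded model is identical
  expect_equal(generate_repertoire(m2, 200, seed = 3)$cdr3_nt,
               generate_repertoire(m, 200, seed = 3)$cdr3_nt)
})

test_that("clonal expansion produces skewed clone sizes", {
  m <- default_model()
  r <- generate_repertoire(m, 800, seed = 17, expansion = 1.0)
  expect_gt(max(r$read_count), 1)
  expect_gt(summary_stats(r)$count_skewness, 1)
  expect_identical(generate_repertoire(m, 800, seed = 17, expansion = 1.0),
                   r)
})
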