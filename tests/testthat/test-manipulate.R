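# Filtering, collapsing and motif search.

test_that("frame filter uses length divisibility and stop codons", {
  nt <- c("TGTGCCAGCTTT", "TGTGCCAGCTTTA", "TGTGCCAGCTTTAAT")  # 12, 13, 15
  r <- repertoire(data.frame(read_count = c(1, 1, 1), cdr3_nt = nt,
                             cdr3_aa = translate_cdr3(nt)))
  kept <- filter_clonotypes(r, frame = "in")
  expect_equal(nchar(kept$cdr3_nt), c(12, 15))
  expect_equal(nchar(filter_clonotypes(r, frame = "out")$cdr3_nt), 13)
  # a stop codon knocks an in-length clonotype out of frame
  r2 <- repertoire(data.frame(read_count = 1, cdr3_nt = "TGTTGA",
                              cdr3_aa = translate_cdr3("TGTTGA")))
  expect_equal(nrow(filter_clonotypes(r2, frame = "in")), 0)
})

test_that("count and gene filters match a linear-scan oracle", {
  r <- toy_rep(c(10, 5, 1))
  expect_equal(filter_clonotypes(r, min_count = 5)$read_count, c(10, 5))
  rr <- random_repertoire(80, seed = 11)
  got <- filter_clonotypes(rr, v_gene = "TRBV3")
  want <- which(strip_allele(rr$v_gene) == "TRBV3")
  expect_equal(as.data.frame(got), as.data.frame(rr[want, ]),
               ignore_attr = TRUE)
  # allele-stripped matching: a *01 query hits all alleles of the gene
  got2 <- filter_clonotypes(rr, v_gene = "TRBV3*01")
  expect_equal(nrow(got2), length(want))
  # exact allele matching when stripping is off
  got3 <- filter_clonotypes(rr, v_gene = "TRBV3*01", strip_alleles = FALSE)
  expect_true(all(got3$v_gene == "TRBV3*01"))
  # filters leave proportions alone unless asked
  expect_equal(got$proportion,
               rr$proportion[want])
  renorm <- filter_clonotypes(rr, v_gene = "TRBV3", renormalize = TRUE)
  if (nrow(renorm) > 0) expect_equal(sum(renorm$proportion), 1)
})

test_that("collapsing merges by key, sums counts, keeps first-seen fields", {
  df <- data.frame(read_count = c(3, 2), cdr3_nt = c("TGTGCC", "TGCGCA"),
                   cdr3_aa = c("CA", "CA"), v_gene = c("TRBV1", "TRBV2"))
  r <- repertoire(df)
  by_aa <- collapse_clonotypes(r, key = "aa")
  expect_equal(nrow(by_aa), 1)
  expect_equal(by_aa$read_count, 5L)
  expect_equal(by_aa$v_gene, "TRBV1")  # first seen
  expect_equal(nrow(collapse_clonotypes(r, key = "nt")), 2)
})

test_that("collapsing equals a dictionary-accumulation oracle and is sorted", {
  for (seed in c(3, 9)) {
    r <- random_repertoire(100, seed = seed, dup_rate = 0.5)
    for (key in c("nt", "aa", "aa+v", "aa+v+j")) {
      got <- collapse_clonotypes(r, key = key)
      k <- clonotype_key(r, key)
      oracle <- tapply(r$read_count, k, sum)
      gk <- clonotype_key(got, key)
      expect_setequal(gk, names(oracle))
      expect_equal(got$read_count, as.integer(oracle[gk]),
                   ignore_attr = TRUE)
      # deterministic order: count desc, key asc
      expect_true(all(diff(got$read_count) <= 0))
      ties <- split(gk, got$read_count)
      expect_true(all(vapply(ties, function(x) !is.unsorted(x), logical(1))))
    }
  }
})

test_that("collapse is idempotent and conserves reads", {
  for (seed in 1:3) {
    r <- random_repertoire(70, seed = seed, dup_rate = 0.4)
    c1 <- collapse_clonotypes(r, "aa")
    expect_identical(as.data.frame(collapse_clonotypes(c1, "aa")),
                     as.data.frame(c1))
    expect_equal(total_reads(c1), total_reads(r))
  }
})

test_that("key-measurable filters commute with collapsing", {
  r <- random_repertoire(80, seed = 21, dup_rate = 0.5)
  # proportions are relative to whichever set they were last recomputed on,
  # so commutation is over clonotypes and counts
  drop_prop <- function(x) as.data.frame(x)[, names(x) != "proportion"]
  # frame is a function of cdr3_nt length => nt-key measurable
  a <- collapse_clonotypes(filter_clonotypes(r, frame = "in"), "nt")
  b <- filter_clonotypes(collapse_clonotypes(r, "nt"), frame = "in")
  expect_equal(drop_prop(a), drop_prop(b), ignore_attr = TRUE)
  # an aa-pattern filter is aa-key measurable
  a2 <- collapse_clonotypes(filter_clonotypes(r, aa_pattern = "C"), "aa")
  b2 <- filter_clonotypes(collapse_clonotypes(r, "aa"), aa_pattern = "C")
  expect_equal(drop_prop(a2), drop_prop(b2), ignore_attr = TRUE)
})

test_that("motif search handles exact, wildcard and mismatch modes", {
  r <- repertoire(data.frame(read_count = c(1, 1),
                             cdr3_nt = c("TGT", "TGC"),
                             cdr3_aa = c("CASSLGF", "CSARDF")))
  expect_equal(motif_search(r, "CASS")$cdr3_aa, "CASSLGF")
  expect_equal(motif_search(r, "CXSS")$cdr3_aa, "CASSLGF")
  # one mismatch lets "CASF" windows through but not "CSAR" (3 mismatches)
  expect_equal(motif_search(r, "CASF", max_mismatch = 1)$cdr3_aa, "CASSLGF")
  expect_equal(nrow(motif_search(r, "CASS", max_mismatch = 1)), 1)
  expect_equal(nrow(motif_search(r, "CASS", max_mismatch = 3)), 2)
  expect_error(motif_search(r, ""), "nonempty")
  expect_equal(nrow(motif_search(r, "CASSLGFCASSLGF")), 0)
})

test_that("motif search equals the sliding-window Hamming oracle", {
  r <- random_repertoire(200, seed = 5, dup_rate = 0)
  for (case in list(list("CASS", 1), list("CXS", 0), list("SS", 1),
                    list("CAXSF", 2))) {
    got <- motif_search(r, case[[1]], on = "aa", max_mismatch = case[[2]])
    want <- motif_oracle(r$cdr3_aa, case[[1]], case[[2]])
    expect_equal(as.data.frame(got), as.data.frame(r[want, ]),
                 ignore_attr = TRUE, label = case[[1]])
  }
})

test_that("mismatch-free wildcard-free motif search is plain substring containment", {
  r <- random_repertoire(150, seed = 8, dup_rate = 0)
  got <- motif_matches(r$cdr3_nt, "TGCA", 0)
  expect_equal(got, grepl("TGCA", r$cdr3_nt, fixed = TRUE))
  skip_if_not_installed("Biostrings")
  hits <- Biostrings::vcountPattern("TGCA",
                                    Biostrings::DNAStringSet(r$cdr3_nt)) > 0
  expect_equal(got, hits)
})
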