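# Shared clonotypes, Jaccard, Morisita, top-cross and multi-sample tables.

# repertoires whose nt keys are the given strings (all valid DNA), counts
# descending in the given order
keyed_rep <- function(keys, counts = rev(seq_along(keys)), id = "K") {
  repertoire(data.frame(read_count = counts, cdr3_nt = keys,
                        stringsAsFactors = FALSE), sample_id = id)
}

test_that("shared clonotypes are the key-set intersection with both counts", {
  a <- keyed_rep(c("AAA", "CCC", "GGG"), c(5, 3, 2), id = "a")
  b <- keyed_rep(c("CCC", "GGG", "TTT"), c(4, 2, 1), id = "b")
  st <- shared_clonotypes(a, b, key = "nt")
  expect_s3_class(st, "shared_table")
  expect_setequal(st$key, c("CCC", "GGG"))
  expect_equal(st[st$key == "CCC", "count.a"], 3)
  expect_equal(st[st$key == "CCC", "count.b"], 4)
  expect_equal(st$n_samples_present, c(2L, 2L))
  disjoint <- shared_clonotypes(keyed_rep("AAA"), keyed_rep("TTT"))
  expect_equal(nrow(disjoint), 0)
})

test_that("jaccard index is intersection over union of key sets", {
  a <- keyed_rep(c("AAA", "CCC", "GGG"))
  b <- keyed_rep(c("CCC", "GGG", "TTT"))
  j <- jaccard_index(a, b, key = "nt")
  expect_equal(j$value, 0.5)
  expect_equal(j$n_shared, 2L)
  expect_equal(jaccard_index(a, a)$value, 1)
  expect_error(jaccard_index(a[0, ], a[0, ]), "empty")
})

test_that("morisita indices reproduce the hand-derived worked example", {
  x <- keyed_rep(c("AAA", "CCC"), c(5, 5))
  cl <- morisita_overlap(x, x, variant = "classic")
  # D_x = D_y = (5*4 + 5*4) / (10*9) = 4/9; C = 2*50 / ((8/9)*100) = 1.125
  expect_equal(cl$value, 1.125, tolerance = 1e-12)
  expect_equal(morisita_overlap(x, x, variant = "horn")$value, 1,
               tolerance = 1e-12)
  # disjoint supports vanish under either variant
  y <- keyed_rep(c("GGG", "TTT"), c(5, 5))
  expect_equal(morisita_overlap(x, y, variant = "classic")$value, 0)
  expect_equal(morisita_overlap(x, y, variant = "horn")$value, 0)
  # identical proportion vectors maximize Horn even at different depths
  x2 <- keyed_rep(c("AAA", "CCC"), c(50, 50))
  expect_equal(morisita_overlap(x, x2, variant = "horn")$value, 1,
               tolerance = 1e-12)
  expect_error(morisita_overlap(keyed_rep("AAA", 1), x, variant = "classic"),
               ">= 2 reads")
})

test_that("morisita indices agree with vegan on random count fixtures", {
  skip_if_not_installed("vegan")
  for (seed in 1:4) {
    a <- random_repertoire(40, seed = seed, id = "a")
    b <- random_repertoire(40, seed = seed + 7, id = "b")
    keys <- union(clonotype_key(a, "nt"), clonotype_key(b, "nt"))
    ka <- collapse_clonotypes(a, "nt"); kb <- collapse_clonotypes(b, "nt")
    xa <- stats::setNames(rep(0, length(keys)), keys)
    xb <- xa
    xa[clonotype_key(ka, "nt")] <- ka$read_count
    xb[clonotype_key(kb, "nt")] <- kb$read_count
    m <- rbind(xa, xb)
    expect_equal(morisita_overlap(a, b, variant = "classic")$value,
                 1 - as.numeric(vegan::vegdist(m, method = "morisita")),
                 tolerance = 1e-10)
    expect_equal(morisita_overlap(a, b, variant = "horn")$value,
                 1 - as.numeric(vegan::vegdist(m, method = "horn")),
                 tolerance = 1e-10)
  }
})

test_that("top-cross intersects the top-k ladders deterministically", {
  a <- keyed_rep(c("AAA", "CCC", "GGG", "TTT"), c(9, 7, 5, 3), id = "a")
  b <- keyed_rep(c("CCC", "CCA", "GGG", "GGT"), c(9, 7, 5, 3), id = "b")
  raw <- top_cross(a, b, steps = c(2, 4), normalize = FALSE)
  expect_equal(raw$value, c(1, 2))
  norm <- top_cross(a, b, steps = c(2, 4), normalize = TRUE)
  expect_equal(norm$value, c(0.5, 0.5))
  same <- top_cross(a, a, steps = c(1, 2, 4), normalize = TRUE)
  expect_equal(same$value, c(1, 1, 1))
  expect_error(top_cross(a, b, steps = integer(0)), "nonempty")
  expect_error(top_cross(a, b, steps = c(4, 2)), "increasing")
  # raw curve is monotone nondecreasing and bounded by min(k, |a|, |b|)
  ra <- random_repertoire(60, seed = 2, id = "a")
  rb <- random_repertoire(60, seed = 5, id = "b")
  steps <- c(1, 5, 10, 20, 50, 100)
  tc <- top_cross(ra, rb, steps = steps, normalize = FALSE)
  expect_true(all(diff(tc$value) >= 0))
  na <- nrow(collapse_clonotypes(ra, "nt"))
  nb <- nrow(collapse_clonotypes(rb, "nt"))
  expect_true(all(tc$value <= pmin(steps, na, nb)))
  # steps beyond both sizes take the whole repertoires: full intersection
  full <- jaccard_index(ra, rb)$n_shared
  expect_equal(tc$value[length(steps)], full)
})

test_that("overlap matrices are symmetric with the documented diagonal", {
  reps <- lapply(1:3, function(s) random_repertoire(50, seed = s,
                                                    id = paste0("S", s)))
  for (meth in c("shared_count", "jaccard", "morisita_horn", "morisita")) {
    m <- overlap_matrix(reps, method = meth, key = "aa")
    expect_equal(m, t(m), label = meth)
  }
  msc <- overlap_matrix(reps, "shared_count", key = "aa")
  expect_equal(unname(diag(msc)),
               vapply(reps, function(r)
                 length(unique(clonotype_key(r, "aa"))), numeric(1)))
  expect_equal(unname(diag(overlap_matrix(reps, "jaccard"))), rep(1, 3))
  # entries equal independently recomputed pairwise values
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(msc[i, j], nrow(shared_clonotypes(reps[[i]], reps[[j]],
                                                   key = "aa")))
  }
  disj <- list(keyed_rep(c("AAA", "CCC"), id = "x"),
               keyed_rep(c("GGG", "TTT"), id = "y"))
  expect_equal(overlap_matrix(disj, "shared_count", key = "nt")["x", "y"], 0)
})

test_that("shared repertoire selects clonotypes by sample prevalence", {
  r1 <- keyed_rep(c("AAA", "CCC", "GGG"), c(5, 4, 3), id = "s1")
  r2 <- keyed_rep(c("AAA", "CCC", "TTT"), c(6, 2, 1), id = "s2")
  r3 <- keyed_rep(c("AAA", "ACG"), c(9, 1), id = "s3")
  st <- shared_repertoire(list(r1, r2, r3), key = "nt", min_samples = 2)
  expect_equal(st$key, c("AAA", "CCC"))
  expect_equal(st$n_samples_present, c(3L, 2L))
  expect_equal(st[["count.s3"]], c(9, 0))
  expect_error(shared_repertoire(list(r1, r2, r3), min_samples = 4),
               "exceeds")
  # restricted to two samples it reproduces shared_clonotypes row-for-row
  a <- random_repertoire(60, seed = 3, id = "a")
  b <- random_repertoire(60, seed = 8, id = "b")
  two <- shared_repertoire(list(a, b), key = "aa", min_samples = 2)
  pair <- shared_clonotypes(a, b, key = "aa")
  expect_equal(two$key, pair$key)
  expect_equal(two[["count.a"]], pair[["count.a"]])
  expect_equal(two[["prop.b"]], pair[["prop.b"]])
})

test_that("pairwise overlaps equal a naive set-arithmetic oracle", {
  for (seed in c(4, 12)) {
    a <- random_repertoire(70, seed = seed, dup_rate = 0.4, id = "a")
    b <- random_repertoire(70, seed = seed + 3, dup_rate = 0.4, id = "b")
    for (key in c("nt", "aa", "aa+v")) {
      ka <- unique(clonotype_key(a, key))
      kb <- unique(clonotype_key(b, key))
      inter <- sum(ka %in% kb)
      expect_equal(nrow(shared_clonotypes(a, b, key)), inter)
      expect_equal(jaccard_index(a, b, key)$value,
                   inter / (length(ka) + length(kb) - inter))
    }
  }
})
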