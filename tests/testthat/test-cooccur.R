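test_that("overlap pmf matches exhaustive enumeration and dhyper", {
  # hand-derivable case: 15 placements of 2 sites against 3 fixed sites
  expect_equal(overlap_pmf(0:2, 6, 3, 2), c(0.2, 0.6, 0.2))
  # outside the feasible support the probability is zero
  expect_identical(overlap_pmf(3, 6, 3, 2), 0)
  expect_identical(overlap_pmf(0, 10, 6, 6), 0)  # lower bound is 2
  # saturation: a ubiquitous taxon forces full overlap
  expect_equal(overlap_pmf(2, 6, 6, 2), 1)

  set.seed(42)
  for (n in 2:10) {
    for (rep in 1:3) {
      n1 <- sample.int(n, 1)
      n2 <- sample.int(n, 1)
      jj <- 0:min(n1, n2)
      expect_equal(overlap_pmf(jj, n, n1, n2), enum_overlap_dist(n, n1, n2),
                   tolerance = 1e-12)
      expect_equal(overlap_pmf(jj, n, n1, n2), stats::dhyper(jj, n1, n - n1, n2),
                   tolerance = 1e-12)
    }
  }
})

test_that("pmf is normalized and symmetric across a parameter grid", {
  grid <- expand.grid(n = c(5, 38, 120, 200), f1 = c(0.1, 0.5, 0.9),
                      f2 = c(0.2, 0.8))
  for (k in seq_len(nrow(grid))) {
    n <- grid$n[k]
    n1 <- round(grid$f1[k] * n)
    n2 <- round(grid$f2[k] * n)
    lo <- max(0, n1 + n2 - n)
    hi <- min(n1, n2)
    expect_equal(sum(overlap_pmf(lo:hi, n, n1, n2)), 1, tolerance = 1e-10)
    expect_equal(overlap_pmf(lo:hi, n, n1, n2),
                 overlap_pmf(lo:hi, n, n2, n1), tolerance = 1e-12)
  }
  expect_error(overlap_pmf(0, 5, 6, 2), "exceeds")
  expect_error(overlap_pmf(0, 5, -1, 2), "non-negative")
})

test_that("pair test tails are inclusive and satisfy the tail identity", {
  t1 <- pair_test(6, 3, 2, 2)
  expect_equal(t1$p_gt, 0.2)
  expect_equal(t1$p_lt, 1)
  t0 <- pair_test(6, 3, 2, 0)
  expect_equal(t0$p_lt, 0.2)
  expect_equal(t0$p_gt, 1)

  set.seed(7)
  for (rep in 1:25) {
    n <- sample(3:60, 1)
    n1 <- sample.int(n, 1)
    n2 <- sample.int(n, 1)
    lo <- max(0, n1 + n2 - n)
    sup <- lo:min(n1, n2)
    j <- sup[sample.int(length(sup), 1)]
    tt <- pair_test(n, n1, n2, j)
    expect_equal(tt$p_lt + tt$p_gt - overlap_pmf(j, n, n1, n2), 1,
                 tolerance = 1e-12)
    sw <- pair_test(n, n2, n1, j)
    expect_equal(tt$p_lt, sw$p_lt, tolerance = 1e-12)
    expect_equal(tt$p_gt, sw$p_gt, tolerance = 1e-12)
  }
  expect_error(pair_test(6, 3, 2, 3), "outside feasible support")
  expect_error(pair_test(10, 6, 6, 1), "outside feasible support")
})

test_that("maximal overlap of an 8/11 pair among 38 samples is extreme", {
  tt <- pair_test(38, 8, 11, 8)
  expect_lt(tt$p_gt, 0.001)
  expect_equal(tt$p_lt, 1)
})

test_that("expected overlap is N1*N2/N", {
  expect_equal(expected_overlap(38, 8, 11), 8 * 11 / 38)
  expect_equal(round(expected_overlap(38, 8, 11), 4), 2.3158)
  expect_lt(expected_overlap(38, 1, 34), 1)   # below the exclusion filter
  expect_identical(expected_overlap(10, 0, 7), 0)
  expect_error(expected_overlap(0, 0, 0), ">= 1")
})

test_that("classification thresholds the correct tail", {
  expect_identical(classify_pair(0.007, 1.000), "negative")
  expect_identical(classify_pair(0.999, 0.004), "positive")
  expect_identical(classify_pair(0.5, 0.6), "random")
  expect_identical(classify_pair(c(0.01, 0.99, 0.5), c(0.99, 0.01, 0.5)),
                   c("negative", "positive", "random"))
  expect_error(classify_pair(0.5, 0.5, alpha = 0), "alpha")
  expect_error(classify_pair(0.5, 1.5), "\\[0, 1\\]")
})

test_that("full analysis tests every pair and applies the exclusion filter", {
  fx <- study_fixture(seed = 2)
  fit <- cooccurrence_analysis(fx$matrix)
  expect_identical(fit$counts[["total"]], 253L)
  expect_identical(nrow(fit$pairs), 253L)
  # excluded pairs are exactly those with expected co-occurrence < 1
  expect_identical(fit$pairs$status == "excluded",
                   fit$pairs$expected_overlap < 1)
  expect_true(all(fit$pairs$classification[fit$pairs$status == "excluded"]
                  == "none"))
  expect_identical(sum(fit$counts[c("positive", "negative", "random")]),
                   sum(fit$pairs$status == "analyzed"))
  # the planted complete-overlap pair is positive
  rn <- fit$pairs[(fit$pairs$taxon_a == "Nostoc" &
                     fit$pairs$taxon_b == "Riccia weinionis") |
                  (fit$pairs$taxon_a == "Riccia weinionis" &
                     fit$pairs$taxon_b == "Nostoc"), ]
  expect_identical(rn$classification, "positive")
  expect_lt(rn$p_gt, 0.001)

  # two singleton taxa are excluded (expected 1/38 << 1)
  m <- make_incidence(c(rep(0, 38), rep(0, 38)), 38, c("A", "B"))
  m[1, "A"] <- 1L; m[2, "B"] <- 1L
  fit2 <- cooccurrence_analysis(m)
  expect_identical(fit2$pairs$status, "excluded")

  expect_error(cooccurrence_analysis(make_incidence(c(1, 0), 2, "A")),
               "at least 2 taxa")
})

test_that("zero-incidence taxa are retained but flagged", {
  m <- make_incidence(c(1, 1, 0, 1, 0, 0, 0, 0, 0), 3, c("A", "B", "C"))
  expect_warning(fit <- cooccurrence_analysis(m), "zero incidence.*C")
  expect_identical(nrow(fit$pairs), 3L)
  c_rows <- fit$pairs$taxon_a == "C" | fit$pairs$taxon_b == "C"
  expect_true(all(fit$pairs$status[c_rows] == "excluded"))
})

test_that("pair table export mirrors the fit", {
  fx <- study_fixture(seed = 2)
  fit <- cooccurrence_analysis(fx$matrix)
  path <- tempfile(fileext = ".csv")
  write_pair_table(fit, path)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_identical(nrow(back), 253L)
  expect_identical(back$classification, fit$pairs$classification)
})
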