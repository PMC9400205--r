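test_that("window grids follow the start/step/truncation convention", {
  spec <- window_spec(c(chr1 = 12500, tiny = 4000, nil = 0))
  w <- make_windows(spec, "chr1")
  expect_equal(nrow(w), 5)
  expect_equal(w$start, c(0L, 2500L, 5000L, 7500L, 10000L))
  expect_equal(w$end[5], 12500L)

  w2 <- make_windows(spec, "tiny")   # shorter than one window
  expect_equal(nrow(w2), 1)          # a single truncated window
  expect_equal(w2$start, 0L)
  expect_equal(w2$end, 4000L)

  expect_equal(nrow(make_windows(spec, "nil")), 0)
  expect_error(make_windows(spec, "nope"), "unknown")
})

test_that("per-site diversity follows the unbiased pairwise estimator", {
  expect_equal(site_pi(2, 4), 2 / 3)
  expect_equal(site_pi(0, 10), 0)
  expect_equal(site_pi(1, 2), 1)
  expect_true(is.na(site_pi(0, 1)))
  # maximal at j = n/2
  n <- 12
  vals <- site_pi(0:n, n)
  expect_equal(which.max(vals) - 1, n / 2)
})

test_that("windowed diversity uses the span denominator and flags empties", {
  # single het site among 1 diploid: j = 1, n = 2 -> site pi = 1
  d <- matrix(1L, 1, 1, dimnames = list(NULL, "S1"))
  gm <- genotype_matrix(
    tibble::tibble(chrom = "c", pos = 10L, ref = "A", alt = "T"), d)
  spec5 <- window_spec(c(c = 5000), size_bp = 5000, step_bp = 5000)
  wp <- windowed_pi(gm, "S1", spec5)
  expect_equal(wp$pi[1], 1 / 5000)
  # doubling the window span halves per-bp diversity
  spec10 <- window_spec(c(c = 10000), size_bp = 10000, step_bp = 10000)
  expect_equal(windowed_pi(gm, "S1", spec10)$pi[1], 1 / 10000)
  # a window with no variants is flagged, not zero-filled
  expect_true(wp$empty[1] == FALSE)
  spec2 <- window_spec(c(c = 10000), size_bp = 5000, step_bp = 5000)
  wp2 <- windowed_pi(gm, "S1", spec2)
  expect_true(wp2$empty[2])
  expect_true(is.na(wp2$pi[2]))
})

test_that("windowed diversity is invariant to sample order", {
  set.seed(5)
  d <- matrix(rbinom(40 * 6, 2, 0.3), 40, 6,
              dimnames = list(NULL, paste0("S", 1:6)))
  gm <- toy_gm(d)
  spec <- window_spec(c(chr1 = 5000))
  a <- windowed_pi(gm, paste0("S", 1:6), spec)
  b <- windowed_pi(gm, paste0("S", sample(1:6)), spec)
  expect_equal(a$pi, b$pi)
})

test_that("Weir-Cockerham components reproduce the hand-derived cases", {
  # fixed difference -> all variance among populations
  fc <- fst_components(0, 1, 0, 0, 4, 4)
  expect_equal(fc$a / (fc$a + fc$b + fc$c), 1)
  # balanced heterozygosity case: a = -1/24, b = 1/24, c = 1/4
  fc <- fst_components(0.5, 0.5, 0.5, 0.5, 4, 4)
  expect_equal(fc$a, -1 / 24)
  expect_equal(fc$b, 1 / 24)
  expect_equal(fc$c, 1 / 4)
  expect_equal(fc$a / (fc$a + fc$b + fc$c), -1 / 6)
  # symmetry under exchanging the populations
  f1 <- fst_components(0.2, 0.7, 0.1, 0.3, 6, 9)
  f2 <- fst_components(0.7, 0.2, 0.3, 0.1, 9, 6)
  expect_equal(f1, f2)
})

test_that("windowed FST equals the scalar component oracle (ratio of sums)", {
  set.seed(21)
  for (rep in 1:5) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    ns <- 30
    d1 <- matrix(rbinom(ns * n1, 2, runif(ns, 0.1, 0.9)), ns, n1)
    d2 <- matrix(rbinom(ns * n2, 2, runif(ns, 0.1, 0.9)), ns, n2)
    d <- cbind(d1, d2)
    colnames(d) <- c(paste0("A", 1:n1), paste0("B", 1:n2))
    gm <- toy_gm(d)
    spec <- window_spec(c(chr1 = 5000), size_bp = 5000, step_bp = 5000)
    wf <- windowed_fst(gm, paste0("A", 1:n1), paste0("B", 1:n2), spec)

    comp <- t(vapply(seq_len(ns), function(i) {
      g1 <- d1[i, ]; g2 <- d2[i, ]
      wc_oracle_site(mean(g1) / 2, mean(g2) / 2,
                     mean(g1 == 1), mean(g2 == 1), n1, n2)
    }, numeric(3)))
    expect_equal(wf$fst[1], sum(comp[, "a"]) / sum(rowSums(comp)),
                 tolerance = 1e-12)
  }
})

test_that("window FST is invariant to site order and permuting samples", {
  set.seed(31)
  d <- matrix(rbinom(50 * 10, 2, runif(50, 0.2, 0.8)), 50, 10,
              dimnames = list(NULL, paste0("S", 1:10)))
  gm <- toy_gm(d)
  spec <- window_spec(c(chr1 = 5000), 5000, 5000)
  a <- windowed_fst(gm, paste0("S", 1:5), paste0("S", 6:10), spec)
  b <- windowed_fst(gm, paste0("S", c(3, 1, 5, 2, 4)),
                    paste0("S", c(9, 10, 6, 8, 7)), spec)
  expect_equal(a$fst, b$fst)
  # all-fixed-difference window hits 1 exactly
  dfix <- cbind(matrix(0L, 20, 5), matrix(2L, 20, 5))
  colnames(dfix) <- paste0("S", 1:10)
  wf <- windowed_fst(toy_gm(dfix), paste0("S", 1:5), paste0("S", 6:10), spec)
  expect_equal(wf$fst[1], 1)
})

test_that("median_stat matches the standard median rules", {
  expect_equal(median_stat(c(0.1, 0.2, 0.3)), 0.2)
  expect_equal(median_stat(c(0.1, 0.3)), 0.2)
  expect_equal(median_stat(c(0.7, NA)), 0.7)
  expect_error(median_stat(c(NA_real_, NA_real_)), "usable")
})

test_that("rank-sum comparison agrees with exact enumeration at small n", {
  # separated samples: U = 0 for the first sample, tiny p
  res <- compare_distributions(1:10, 11:20)
  expect_equal(unname(res$statistic), 0)
  expect_lt(res$p_value, 1e-3)
  # identical samples: p ~ 1
  res2 <- compare_distributions(1:10, 1:10)
  expect_gt(res2$p_value, 0.9)
  # U statistic equals the pair-count definition, checked by enumeration
  a <- c(1.2, 3.4, 5.1); b <- c(2.2, 0.8, 4.0)
  res3 <- compare_distributions(a, b)
  u_enum <- sum(outer(a, b, ">"))
  expect_equal(unname(res3$statistic), u_enum)
  # the normal-approximation p is conservative but consistent with the
  # exact tail: exact p from enumerating all 20 rank assignments
  exact_p <- wilcox.test(a, b, exact = TRUE)$p.value
  expect_equal(res3$p_value > 0.05, exact_p > 0.05)
})
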