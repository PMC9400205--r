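make_cov <- function(f_depths, m_depths, n_windows = 20, chrom = "c1") {
  # constant depths per sample across n_windows windows
  samples <- c(paste0("F", seq_along(f_depths)),
               paste0("M", seq_along(m_depths)))
  depth <- matrix(rep(c(f_depths, m_depths), each = n_windows),
                  n_windows, length(samples), dimnames = list(NULL, samples))
  cov <- dplyr::bind_cols(
    tibble::tibble(chrom = chrom,
                   start = (seq_len(n_windows) - 1L) * 1000L,
                   end = seq_len(n_windows) * 1000L),
    tibble::as_tibble(depth))
  meta <- tibble::tibble(sample = samples, population = "P",
                         sex = rep(c("F", "M"), c(length(f_depths),
                                                  length(m_depths))))
  list(cov = cov, meta = meta)
}

test_that("sex-group window means ignore unknown-sex samples", {
  x <- make_cov(c(40, 40), c(20, 20))
  gm <- group_mean_coverage(x$cov, x$meta)
  expect_equal(gm$f_mean, rep(40, 20))
  expect_equal(gm$m_mean, rep(20, 20))
  # add an unknown-sex sample: result unchanged
  x$cov$U1 <- 99
  x$meta <- dplyr::bind_rows(x$meta, tibble::tibble(
    sample = "U1", population = "P", sex = "unknown"))
  gm2 <- group_mean_coverage(x$cov, x$meta)
  expect_equal(gm2$f_mean, gm$f_mean)
  expect_equal(gm2$m_mean, gm$m_mean)
  # a sex group with no samples is an error
  expect_error(
    group_mean_coverage(x$cov, dplyr::filter(x$meta, sex != "M")),
    "male")
})

test_that("log2 ratio arithmetic matches the stated rule", {
  gm <- tibble::tibble(chrom = "c", start = 0L, end = 1000L,
                       f_mean = 40, m_mean = 20)
  r <- fm_log_ratio(gm, sex_scan_params(pseudocount = 1e-9))
  expect_equal(r$log2_ratio, 1, tolerance = 1e-6)
  r2 <- fm_log_ratio(dplyr::mutate(gm, f_mean = 20), sex_scan_params())
  expect_equal(r2$log2_ratio, 0)
  # zero female depth on a Y-like window: finite and well below -1
  r3 <- fm_log_ratio(dplyr::mutate(gm, f_mean = 0, m_mean = 25),
                     sex_scan_params(pseudocount = 0.1))
  expect_equal(r3$log2_ratio, log2(0.1 / 25.1))
  expect_lte(r3$log2_ratio, -1)
  # windows under the male depth floor are unusable
  r4 <- fm_log_ratio(dplyr::mutate(gm, m_mean = 0.5), sex_scan_params())
  expect_false(r4$usable)
})

test_that("chromosome classification follows the log2 bands", {
  x <- make_cov(c(40, 40), c(20, 20))                  # log2 = 1 -> X
  calls_x <- classify_chromosomes(x$cov, x$meta)$calls
  expect_equal(calls_x$call, "X-linked")

  a <- make_cov(c(30, 30), c(30, 30))                  # log2 = 0 -> autosome
  expect_equal(classify_chromosomes(a$cov, a$meta)$calls$call, "autosome")

  y <- make_cov(c(0.4, 0.4), c(10, 10))                # strongly negative -> Y
  expect_equal(classify_chromosomes(y$cov, y$meta)$calls$call, "Y-linked")

  mid <- make_cov(c(30, 30), c(30, 30) / 2^0.5)        # m ~ 0.5: no band
  expect_equal(classify_chromosomes(mid$cov, mid$meta)$calls$call,
               "undetermined")

  few <- make_cov(c(40, 40), c(20, 20), n_windows = 5) # < 10 usable windows
  expect_equal(classify_chromosomes(few$cov, few$meta)$calls$call,
               "undetermined")
})

test_that("swapping the sex labels negates the ratios and mirrors X calls", {
  cfg <- sim_config(seed = 5, chromosomes = tibble::tibble(
    name = c("auto1", "xchr"), length = c(2e5, 2e5),
    type = c("autosome", "X")))
  sc <- simulate_coverage(cfg)
  swapped <- sc$meta |>
    dplyr::mutate(sex = dplyr::recode(sex, F = "M", M = "F"))
  r1 <- fm_log_ratio(group_mean_coverage(sc$coverage, sc$meta),
                     sex_scan_params())
  r2 <- fm_log_ratio(group_mean_coverage(sc$coverage, swapped),
                     sex_scan_params())
  # delta asymmetry is negligible at 17x depth
  expect_equal(r2$log2_ratio, -r1$log2_ratio, tolerance = 1e-2)
  calls <- classify_chromosomes(sc$coverage, swapped)$calls
  # the true X now looks Y-like (males at double dose of "females")
  expect_equal(calls$call[calls$chrom == "xchr"], "Y-linked")
})

test_that("simulated autosome, X and Y are classified correctly with the
           expected ratio levels", {
  cfg <- sim_config(seed = 17, chromosomes = tibble::tibble(
    name = c("a1", "x1", "y1"), length = c(5e5, 5e5, 2e5),
    type = c("autosome", "X", "Y")))
  sc <- simulate_coverage(cfg)
  res <- classify_chromosomes(sc$coverage, sc$meta)
  calls <- res$calls
  expect_equal(calls$call[calls$chrom == "a1"], "autosome")
  expect_equal(calls$call[calls$chrom == "x1"], "X-linked")
  expect_equal(calls$call[calls$chrom == "y1"], "Y-linked")
  # raw F:M ratio levels: ~1 on the autosome, ~2 on X
  gw <- group_mean_coverage(sc$coverage, sc$meta)
  ratio <- gw$f_mean / gw$m_mean
  expect_equal(median(ratio[gw$chrom == "a1"]), 1, tolerance = 0.05)
  expect_equal(median(ratio[gw$chrom == "x1"]), 2, tolerance = 0.1)
})
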