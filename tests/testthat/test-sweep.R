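test_that("diversity ratio follows the pseudocount rule and orientation", {
  expect_equal(pi_ratio(4e-3, 1e-3, 1e-9), 4, tolerance = 1e-4)
  expect_equal(pi_ratio(3e-3, 0, 1e-5), (3e-3 + 1e-5) / 1e-5)
  expect_equal(pi_ratio(2e-3, 2e-3), 1)
  expect_true(is.na(pi_ratio(NA, 1e-3)))
  expect_error(pi_ratio(1, 1, epsilon = 0), "positive")
})

test_that("the upper-quantile rule flags by order statistic, ties never flag", {
  v <- sample(1:100)                      # distinct values
  m <- quantile_outliers(v, 0.95)
  expect_equal(sum(m), 5)
  expect_setequal(v[m], 96:100)
  # all equal -> nothing exceeds the threshold
  expect_equal(sum(quantile_outliers(rep(7, 40), 0.95)), 0)
  # flagged fraction never exceeds 1 - q (random tied data)
  set.seed(8)
  for (i in 1:20) {
    x <- sample(1:10, 200, replace = TRUE)
    expect_lte(mean(quantile_outliers(x, 0.95)), 0.05)
  }
  expect_error(quantile_outliers(1:5, 0.95), "usable windows")
})

test_that("outlier intersection is a logical AND that drops excluded windows", {
  expect_equal(intersect_outliers(c(TRUE, FALSE, TRUE), c(TRUE, TRUE, FALSE)),
               c(TRUE, FALSE, FALSE))
  expect_equal(intersect_outliers(c(TRUE, NA), c(TRUE, TRUE)),
               c(TRUE, FALSE))
  expect_error(intersect_outliers(c(TRUE), c(TRUE, FALSE)), "mismatch")
})

test_that("flagged windows merge when overlapping or book-ended only", {
  w <- tibble::tibble(
    chrom = c("c1", "c1", "c1", "c2"),
    start = c(0L, 2500L, 10000L, 0L),
    end = c(5000L, 7500L, 15000L, 5000L),
    fst = c(0.5, 0.8, 0.3, 0.9)
  )
  r <- merge_regions(w, rep(TRUE, 4))
  expect_equal(nrow(r), 3)
  r1 <- r[r$chrom == "c1" & r$start == 0, ]
  expect_equal(r1$end, 7500L)           # overlapping windows merged
  expect_equal(r1$n_windows, 2L)
  expect_equal(r1$peak_fst, 0.8)        # peak statistic = member max
  expect_true(any(r$chrom == "c2"))     # different chrom never merges
  # book-ended windows merge too
  wb <- tibble::tibble(chrom = "c1", start = c(0L, 5000L),
                       end = c(5000L, 10000L), fst = c(1, 2))
  expect_equal(nrow(merge_regions(wb, c(TRUE, TRUE))), 1)
  # nothing flagged -> empty region set
  expect_equal(nrow(merge_regions(w, rep(FALSE, 4))), 0)
})

test_that("gene overlap is half-open and deduplicates the gene list", {
  regions <- tibble::tibble(chrom = "c1", start = c(0L, 9000L),
                            end = c(7500L, 12000L))
  genes <- tibble::tibble(
    chrom = "c1",
    start = c(7400L, 7500L, 6000L),
    end = c(9500L, 9000L, 7000L),
    gene_id = c("gA", "gB", "gC")
  )
  og <- overlap_genes(regions, genes)
  # gA overlaps region 1 (1 bp at 7400..7500) and region 2; counted once
  expect_setequal(og$genes, c("gA", "gC"))
  # gB starts exactly at region 1's end -> no overlap under half-open
  expect_false("gB" %in% og$genes)
  expect_equal(og$regions$n_genes, c(2L, 1L))
})

test_that("hypergeometric enrichment matches direct combinatorics, BH applied", {
  cats <- tibble::tibble(gene_id = paste0("g", 1:100),
                         category = rep(c("K1", "rest"), c(10, 90)))
  res <- enrichment_test(paste0("g", 1:5), paste0("g", 1:100), cats)
  k1 <- res[res$category == "K1", ]
  expect_equal(k1$p_value, choose(10, 5) / choose(100, 5), tolerance = 1e-10)
  expect_equal(k1$k, 5L)
  # k = 0 -> p = 1
  res0 <- enrichment_test(paste0("g", 95:99), paste0("g", 1:100),
                          cats |> dplyr::filter(category == "K1"))
  expect_equal(res0$p_value, 1)
  # single category: BH leaves p unchanged; fdr >= p always
  expect_equal(res0$fdr, res0$p_value)
  expect_true(all(res$fdr >= res$p_value))
  expect_error(enrichment_test("g1", character(), cats), "background")
  expect_error(enrichment_test("zz", paste0("g", 1:10), cats), "subset")
})

test_that("an injected sweep is recovered by the outlier intersection", {
  # 5-Mb genome, 200-kb sweep at intensity 0.9 in the target population
  cfg <- sim_config(
    seed = 2024,
    chromosomes = tibble::tibble(name = "chr1", length = 5e6,
                                 type = "autosome"),
    populations = tibble::tibble(label = c("REF", "TGT"), n = c(10, 10),
                                 f = c(0.03, 0.03)),
    site_density = 0.004,
    sweeps = tibble::tibble(chrom = "chr1", start = 2e6, end = 2.2e6,
                            target = "TGT", alpha = 0.9)
  )
  sim <- simulate_genotypes(cfg)
  spec <- window_spec(c(chr1 = 5e6))
  ws <- window_stats(sim$gm, sim$meta, spec,
                     contrasts = list(c("REF", "TGT")))
  sc <- sweep_scan(ws, "REF", "TGT")
  w <- sc$windows
  truth <- w$start >= 2e6 & w$end <= 2.2e6   # windows fully inside the sweep
  expect_gte(mean(w$candidate[truth]), 0.80)           # recall
  expect_lte(mean(w$candidate[!truth]), 0.01)          # false flags
  # a merged region overlaps the truth interval
  expect_true(any(sc$regions$start < 2.2e6 & sc$regions$end > 2e6))

  # monotonicity: stronger sweeps never flag fewer truth windows
  flagged_at <- function(alpha) {
    cfg_a <- cfg
    cfg_a$sweeps$alpha <- alpha
    sim_a <- simulate_genotypes(cfg_a)
    ws_a <- window_stats(sim_a$gm, sim_a$meta, spec,
                         contrasts = list(c("REF", "TGT")))
    sum(sweep_scan(ws_a, "REF", "TGT")$windows$candidate[truth])
  }
  counts <- vapply(c(0.5, 0.7, 0.9), flagged_at, numeric(1))
  expect_true(all(diff(counts) >= 0))
})
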