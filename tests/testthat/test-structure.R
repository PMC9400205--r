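test_that("IBS distance matches the allele-sharing definition", {
  # identical samples -> 0; opposite homozygotes -> 1; one het step -> 0.5
  d <- cbind(a = c(0L, 1L, 2L), b = c(0L, 1L, 2L), c = c(2L, 1L, 0L))
  dm <- ibs_distance(toy_gm(d))
  expect_equal(dm$d["a", "b"], 0)
  expect_equal(dm$d["a", "a"], 0)
  expect_equal(dm$d["a", "c"], 2 / 3)   # sites differ by 2,0,2 over 3 sites
  single <- ibs_distance(toy_gm(cbind(a = 0L, b = 1L)))
  expect_equal(single$d["a", "b"], 0.5)
  full <- ibs_distance(toy_gm(cbind(a = c(0L, 0L), b = c(2L, 2L))))
  expect_equal(full$d["a", "b"], 1)
  # missing genotypes shrink the per-pair site count
  dm2 <- ibs_distance(toy_gm(cbind(a = c(0L, NA), b = c(1L, 2L))))
  expect_equal(dm2$n_sites["a", "b"], 1)
  expect_equal(dm2$d["a", "b"], 0.5)
  # symmetric with zero diagonal
  expect_true(isSymmetric(dm$d))
  expect_equal(diag(dm$d), c(a = 0, b = 0, c = 0))
  # a pair with no shared called site is an error naming the pair
  expect_error(ibs_distance(toy_gm(cbind(a = c(0L, NA), b = c(NA, 1L)))),
               "a / b")
})

test_that("neighbor-joining solves the three-point configuration exactly", {
  m <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  res <- nj_tree(m)
  bl <- setNames(res$tree$edge.length[order(res$tree$edge[, 2])][
    seq_along(res$tree$tip.label)], res$tree$tip.label)
  expect_equal(sort(unname(bl)), c(0, 2, 4))
  expect_equal(unname(bl["A"]), 0)
  expect_equal(unname(bl["B"]), 2)
  expect_equal(unname(bl["C"]), 4)
})

test_that("NJ recovers additive four-taxon trees, topology and lengths", {
  # tree ((A:1,B:2):1,(C:3,D:4)) -> additive distances
  m <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  m["A", "B"] <- m["B", "A"] <- 3
  m["A", "C"] <- m["C", "A"] <- 5
  m["A", "D"] <- m["D", "A"] <- 6
  m["B", "C"] <- m["C", "B"] <- 6
  m["B", "D"] <- m["D", "B"] <- 7
  m["C", "D"] <- m["D", "C"] <- 7
  res <- nj_tree(m)
  # the reconstructed path-length matrix reproduces the input exactly
  expect_equal(cophenetic(res$tree)[LETTERS[1:4], LETTERS[1:4]], m,
               tolerance = 1e-10)
  # AB|CD split present
  expect_equal(as.numeric(ape::dist.topo(res$tree, ape::read.tree(
    text = "((A:1,B:2):1,C:3,D:4);"))), 0)
})

test_that("NJ is exact on random additive matrices up to 8 leaves", {
  for (n in c(5, 6, 8)) {
    for (seed in 1:3) {
      ra <- random_additive(n, seed = 100 * n + seed)
      res <- nj_tree(ra$d)
      labs <- rownames(ra$d)
      expect_equal(cophenetic(res$tree)[labs, labs], ra$d,
                   tolerance = 1e-8)
      expect_equal(as.numeric(ape::dist.topo(ape::unroot(res$tree),
                                         ape::unroot(ra$tree))), 0)
    }
  }
})

test_that("taxon order does not change the NJ tree", {
  ra <- random_additive(6, seed = 7)
  perm <- sample(rownames(ra$d))
  res1 <- nj_tree(ra$d)
  res2 <- nj_tree(ra$d[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(res1$tree),
                                     ape::unroot(res2$tree))), 0)
})

test_that("newick serialisation round-trips, quoting awkward labels", {
  ra <- random_additive(5, seed = 3)
  res <- nj_tree(ra$d)
  s <- to_newick(res)
  rt <- from_newick(s)
  expect_setequal(rt$tip.label, res$tree$tip.label)
  expect_equal(cophenetic(rt)[rownames(ra$d), rownames(ra$d)],
               cophenetic(res$tree)[rownames(ra$d), rownames(ra$d)],
               tolerance = 1e-6)
  # labels with spaces survive via quoting
  tr <- res$tree
  tr$tip.label[1] <- "sample one"
  s2 <- to_newick(tr)
  expect_match(s2, "'sample one'", fixed = TRUE)
  expect_true("sample one" %in% from_newick(s2)$tip.label)
})

test_that("PCA separates fixed groups and duplicates coincide", {
  # two groups fixed for alternate alleles at every site
  d <- cbind(matrix(0L, 30, 4), matrix(2L, 30, 4))
  colnames(d) <- paste0("S", 1:8)
  p <- pca_genotypes(toy_gm(d), k = 2)
  co <- p$coordinates
  g1 <- co$PC1[1:4]; g2 <- co$PC1[5:8]
  expect_lt(max(abs(g1 - g1[1])), 1e-8)     # zero within-group spread
  expect_lt(max(abs(g2 - g2[1])), 1e-8)
  expect_gt(abs(g1[1] - g2[1]), 0.1)        # PC1 separates the groups
  expect_true(all(p$eigenvalues >= 0))

  # duplicated sample lands on identical coordinates
  set.seed(2)
  dd <- matrix(rbinom(50 * 5, 2, 0.4), 50, 5)
  dd <- cbind(dd, dd[, 5])
  colnames(dd) <- paste0("S", 1:6)
  p2 <- pca_genotypes(toy_gm(dd), k = 2)
  expect_equal(unlist(p2$coordinates[5, -1]), unlist(p2$coordinates[6, -1]),
               tolerance = 1e-8)
  expect_error(pca_genotypes(toy_gm(dd), k = 6), "at most")
})

test_that("PCA coordinates are invariant (up to sign) to sample order", {
  set.seed(4)
  d <- matrix(rbinom(80 * 6, 2, runif(80, 0.2, 0.8)), 80, 6,
              dimnames = list(NULL, paste0("S", 1:6)))
  gm <- toy_gm(d)
  p1 <- pca_genotypes(gm, k = 2)
  perm <- sample(paste0("S", 1:6))
  p2 <- pca_genotypes(gm, samples = perm, k = 2)
  a <- p1$coordinates[match(perm, p1$coordinates$sample), ]
  for (pc in c("PC1", "PC2")) {
    expect_true(isTRUE(all.equal(a[[pc]], p2$coordinates[[pc]],
                                 tolerance = 1e-6)) ||
                isTRUE(all.equal(a[[pc]], -p2$coordinates[[pc]],
                                 tolerance = 1e-6)))
  }
  expect_equal(sum(p1$eigenvalues), sum(p2$eigenvalues), tolerance = 1e-8)
})

test_that("admixed individuals project between their source clusters", {
  cfg <- sim_config(
    seed = 31,
    chromosomes = tibble::tibble(name = "chr1", length = 4e5,
                                 type = "autosome"),
    populations = tibble::tibble(label = c("P1", "P2", "P3"),
                                 n = c(8, 8, 8), f = c(0.12, 0.12, 0.12)),
    site_density = 0.01,
    admixed = tibble::tibble(
      sample = c("AD1", "AD2", "AD3"), sex = "F",
      q_P1 = c(0.5, 0.35, 0.65), q_P2 = c(0.5, 0.65, 0.35), q_P3 = 0)
  )
  sim <- simulate_genotypes(cfg)
  p <- pca_genotypes(sim$gm, k = 2)
  co <- p$coordinates
  xy <- as.matrix(co[, c("PC1", "PC2")])
  rownames(xy) <- co$sample
  cent <- function(pop) {
    ids <- sim$meta$sample[sim$meta$population == pop]
    colMeans(xy[ids, , drop = FALSE])
  }
  c1 <- cent("P1"); c2 <- cent("P2")
  axis <- (c2 - c1) / sqrt(sum((c2 - c1)^2))
  proj <- function(v) sum((v - c1) * axis)
  lo <- 0; hi <- proj(c2)
  for (ad in c("AD1", "AD2", "AD3")) {
    t <- proj(xy[ad, ])
    expect_gt(t, lo)
    expect_lt(t, hi)
  }
})
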