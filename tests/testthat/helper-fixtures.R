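# Shared fixture builders: everything is generated in code at test time.

# Minimal genotype matrix from a dosage matrix (positions 100, 200, ...)
toy_gm <- function(dosage, chrom = "chr1", alt = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- paste0("S", seq_len(ncol(dosage)))
  }
  n <- nrow(dosage)
  genotype_matrix(
    sites = tibble::tibble(
      chrom = chrom, pos = seq_len(n) * 100L, ref = "A",
      alt = if (is.null(alt)) rep("T", n) else alt
    ),
    dosage = dosage
  )
}

# Hand-written 3-site, 2-sample VCF used by the parsing tests
write_toy_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=QD,Number=1,Type=Float,Description="Qual by depth">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="Mapping quality">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "A", "B"), collapse = "\t"),
    "chr1\t100\t.\tA\tG\t50\tPASS\tQD=25.0;MQ=60.0\tGT:GQ\t0/0:99\t0|1:45",
    "chr1\t200\t.\tC\tT\t50\tPASS\tQD=1.5\tGT:GQ\t0/1:20\t./.:.",
    "chr1\t300\t.\tG\tA,C\t50\tPASS\tMQ=30.0\tGT:GQ\t1/1:60\t1/2:10"
  ), path)
  path
}

# Independent scalar Weir-Cockerham oracle: the r = 2 component formulas
# evaluated one site at a time, written independently of the package's
# vectorised implementation.
wc_oracle_site <- function(p1, p2, h1, h2, n1, n2) {
  nbar <- mean(c(n1, n2))
  nc <- (2 * nbar - (n1 * n1 + n2 * n2) / (2 * nbar))
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - hbar * (2 * nbar - 1) / (4 * nbar))
  c(a = a, b = b, c = hbar / 2)
}

# Independent HWE oracle: Levene probabilities from the closed-form
# factorial expression, full enumeration over heterozygote counts.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  na <- 2 * n_aa + n_Aa
  na <- min(na, 2 * n - na)
  if (na == 0) return(1)
  h_vals <- seq(na %% 2, na, by = 2)
  logp <- vapply(h_vals, function(h) {
    naa <- (na - h) / 2
    nAA <- n - h - naa
    lfactorial(n) - lfactorial(nAA) - lfactorial(h) - lfactorial(naa) +
      h * log(2) + lfactorial(na) + lfactorial(2 * n - na) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp)
  obs <- p[match(n_Aa, h_vals)]
  sum(p[p <= obs * (1 + 1e-12)])
}

# Random additive distance matrix from a random topology with known
# branch lengths; returns the matrix and the generating tree.
random_additive <- function(n_leaves, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_leaves, rooted = FALSE,
                   br = function(k) runif(k, 0.1, 1))
  tr$tip.label <- paste0("L", seq_len(n_leaves))
  list(d = cophenetic(tr), tree = tr)
}
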