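#' Exact test of Hardy-Weinberg equilibrium (Levene's conditional test)
#'
#' Conditional on the observed allele counts, the number of heterozygotes
#' under Hardy-Weinberg proportions follows Levene's distribution
#'
#' \deqn{P(h \mid n, n_a) = \frac{n!\,2^h\,n_a!\,(2n-n_a)!}
#'       {n_{AA}!\,h!\,n_{aa}!\,(2n)!}}
#'
#' where `n` is the number of diploids and `n_a` the count of the rarer
#' allele. The two-sided p-value sums the probabilities of all
#' heterozygote counts no more probable than the observed one (the
#' standard exact rule; no mid-p adjustment). The statistic is symmetric
#' in the allele labels. Probabilities are computed in log space by the
#' ratio recurrence between successive heterozygote counts, so the test
#' is stable for thousands of samples.
#'
#' @param n_aa_major Count of major-allele homozygotes.
#' @param n_het Count of heterozygotes.
#' @param n_aa_minor Count of minor-allele homozygotes. (Arguments may be
#'   given in either homozygote order.)
#' @return The exact p-value in `[0, 1]`; monomorphic samples give 1.
#' @examples
#' hwe_exact_test(0, 4, 0)  # 22/70
#' @export
hwe_exact_test <- function(n_aa_major, n_het, n_aa_minor) {
  counts <- c(n_aa_major, n_het, n_aa_minor)
  if (any(counts < 0) || sum(counts) < 1) {
    abort("genotype counts must be non-negative with at least one sample")
  }
  n <- sum(counts)
  n_a <- 2 * n_aa_minor + n_het          # one allele's count
  n_a <- min(n_a, 2 * n - n_a)           # rarer allele (symmetry)
  if (n_a == 0) return(1)

  # valid heterozygote counts share the parity of n_a
  h_vals <- seq(n_a %% 2, n_a, by = 2)
  # log P(h) up to a constant, via the recurrence
  #   P(h+2)/P(h) = 4 * n_AA(h) * n_aa(h) / ((h+2) * (h+1))
  logp <- numeric(length(h_vals))
  for (i in seq_along(h_vals)[-1]) {
    h <- h_vals[i - 1]
    naa <- (n_a - h) / 2                  # minor homozygotes at h
    nAA <- n - (h + naa)
    logp[i] <- logp[i - 1] + log(4 * nAA * naa) - log((h + 2) * (h + 1))
  }
  logp <- logp - max(logp)
  p_h <- exp(logp) / sum(exp(logp))

  h_obs <- n_het
  obs_i <- match(h_obs, h_vals)
  if (is.na(obs_i)) abort("heterozygote count inconsistent with allele count")
  min(1, sum(p_h[p_h <= p_h[obs_i] * (1 + 1e-12)]))
}

#' Per-site HWE p-values from a genotype matrix
#'
#' @param gm A [genotype_matrix()].
#' @param samples Optional sample ids to test on (default all).
#' @return Numeric vector of exact p-values, one per site; sites with no
#'   called genotypes give `NA`.
#' @export
hwe_pvalues <- function(gm, samples = NULL) {
  d <- if (is.null(samples)) gm$dosage else gm$dosage[, samples, drop = FALSE]
  n0 <- rowSums(d == 0L, na.rm = TRUE)
  n1 <- rowSums(d == 1L, na.rm = TRUE)
  n2 <- rowSums(d == 2L, na.rm = TRUE)
  vapply(seq_len(nrow(d)), function(i) {
    if (n0[i] + n1[i] + n2[i] == 0) return(NA_real_)
    hwe_exact_test(n0[i], n1[i], n2[i])
  }, numeric(1))
}
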