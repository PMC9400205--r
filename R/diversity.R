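#' Per-site nucleotide diversity
#'
#' The unbiased pairwise-difference estimator at a biallelic site:
#' \deqn{\hat\pi = \frac{2 j (n - j)}{n (n - 1)}}
#' with `j` alternate alleles among `n` sampled alleles. Equals the
#' probability that two alleles drawn without replacement differ.
#'
#' @param j Alternate-allele count(s), `0 <= j <= n`.
#' @param n Total sampled alleles (twice the called diploids); sites with
#'   `n < 2` are undefined and return `NA`.
#' @return Numeric vector of per-site diversity in `[0, 1]`.
#' @examples
#' site_pi(2, 4)  # 2/3
#' site_pi(1, 2)  # 1: the two alleles always differ
#' @export
site_pi <- function(j, n) {
  stopifnot(all(j >= 0 & j <= n, na.rm = TRUE))
  out <- 2 * j * (n - j) / (n * (n - 1))
  out[n < 2] <- NA_real_
  out
}

#' Sliding-window nucleotide diversity
#'
#' Per-window per-bp diversity for one population:
#' \deqn{\pi_w = \sum_{\mathrm{sites} \in w} \hat\pi_s / (end_w - start_w)}
#' Non-variant positions contribute zero, so the denominator is the full
#' window span (the windowed-pi convention of the usual VCF tools; set
#' `denominator = "variant"` to divide by the variant count instead).
#' Windows containing no usable variant are flagged `empty` and should be
#' excluded from medians and quantiles.
#'
#' @param gm A filtered [genotype_matrix()].
#' @param samples Sample ids of the population.
#' @param spec A [window_spec()].
#' @param denominator `"span"` (default) or `"variant"`.
#' @return A tibble `chrom`, `start`, `end`, `n_variants`, `pi`, `empty`.
#' @export
windowed_pi <- function(gm, samples, spec, denominator = c("span", "variant")) {
  denominator <- match.arg(denominator)
  if (length(samples) == 0) abort("empty population")
  windows <- make_all_windows(spec)
  d <- gm$dosage[, samples, drop = FALSE]
  n_alleles <- 2 * rowSums(!is.na(d))
  j <- rowSums(d, na.rm = TRUE)
  pi_s <- site_pi(j, n_alleles)
  usable <- !is.na(pi_s)
  map <- site_window_map(windows, gm$sites$chrom[usable],
                         gm$sites$pos[usable] - 1L)
  pi_sum <- rep(0, nrow(windows))
  n_var <- rep(0L, nrow(windows))
  if (nrow(map) > 0) {
    sums <- tapply(pi_s[usable][map$site], map$window, sum)
    cnts <- tapply(map$site, map$window, length)
    wid <- as.integer(names(sums))
    pi_sum[wid] <- as.numeric(sums)
    n_var[wid] <- as.integer(cnts)
  }
  denom <- if (denominator == "span") windows$end - windows$start else n_var
  windows |>
    mutate(n_variants = n_var,
           pi = ifelse(n_var > 0, pi_sum / denom, NA_real_),
           empty = n_var == 0)
}
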