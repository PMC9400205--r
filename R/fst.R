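#' Weir-Cockerham variance components at a site (two populations)
#'
#' The Weir & Cockerham (1984) analysis-of-variance estimator partitions
#' allele-frequency variance into among-population (`a`),
#' among-individual-within-population (`b`) and within-individual (`c`)
#' components. For `r = 2` populations with sample sizes `n_i`, alternate
#' frequencies `p_i` and observed heterozygote fractions `h_i`:
#' \deqn{\bar n = (n_1 + n_2)/2,\quad
#'       n_c = 2\bar n - (n_1^2 + n_2^2)/(2\bar n)}
#' \deqn{\bar p = \sum n_i p_i / (2\bar n),\quad
#'       s^2 = \sum n_i (p_i - \bar p)^2 / \bar n,\quad
#'       \bar h = \sum n_i h_i / (2\bar n)}
#' \deqn{a = \frac{\bar n}{n_c}\Big[s^2 - \frac{1}{\bar n - 1}
#'       \big(\bar p(1-\bar p) - \tfrac{1}{2}s^2 - \tfrac{1}{4}\bar h\big)\Big]}
#' \deqn{b = \frac{\bar n}{\bar n - 1}\Big[\bar p(1-\bar p) - \tfrac12 s^2
#'       - \frac{2\bar n - 1}{4\bar n}\bar h\Big],\qquad c = \bar h / 2}
#' The per-site estimator is `a / (a + b + c)`; windows combine sites as a
#' ratio of sums. All arguments are vectorised over sites.
#'
#' @param p1,p2 Alternate-allele frequencies per population.
#' @param h1,h2 Observed heterozygote fractions per population.
#' @param n1,n2 Called diploid counts per population (`>= 1`).
#' @return A tibble with columns `a`, `b`, `c`; rows with `n_c <= 0` or
#'   `nbar <= 1` (component triple undefined) are `NA`.
#' @examples
#' fst_components(0, 1, 0, 0, 4, 4)            # fixed difference: ratio 1
#' fst_components(0.5, 0.5, 0.5, 0.5, 4, 4)    # a = -1/24, b = 1/24, c = 1/4
#' @export
fst_components <- function(p1, p2, h1, h2, n1, n2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  bad <- !is.finite(nc) | nc <= 0 | nbar <= 1
  a[bad] <- NA_real_; b[bad] <- NA_real_; cc[bad] <- NA_real_
  tibble(a = a, b = b, c = cc)
}

# Per-site frequencies/heterozygosity/sample sizes for one population.
pop_site_freq <- function(gm, samples) {
  d <- gm$dosage[, samples, drop = FALSE]
  n <- rowSums(!is.na(d))
  list(n = n,
       p = ifelse(n > 0, rowSums(d, na.rm = TRUE) / (2 * n), NA_real_),
       h = ifelse(n > 0, rowSums(d == 1L, na.rm = TRUE) / n, NA_real_))
}

#' Sliding-window weighted Weir-Cockerham FST
#'
#' Weighted (ratio-of-sums) window estimate
#' \deqn{\hat F_{ST}(w) = \sum_{s \in w} a_s \Big/ \sum_{s \in w} (a_s + b_s + c_s)}
#' over sites usable in both populations. Windows with no usable site or
#' non-positive denominator are excluded (`NA`). Negative estimates are
#' retained — clamping would distort the outlier quantile downstream.
#'
#' @param gm A filtered [genotype_matrix()].
#' @param pop_a,pop_b Sample-id vectors for the two populations.
#' @param spec A [window_spec()].
#' @return A tibble `chrom`, `start`, `end`, `n_variants`, `fst`,
#'   `excluded`.
#' @export
windowed_fst <- function(gm, pop_a, pop_b, spec) {
  if (length(pop_a) == 0 || length(pop_b) == 0) {
    abort("both populations need at least one sample")
  }
  windows <- make_all_windows(spec)
  fa <- pop_site_freq(gm, pop_a)
  fb <- pop_site_freq(gm, pop_b)
  comp <- fst_components(fa$p, fb$p, fa$h, fb$h, fa$n, fb$n)
  num <- comp$a
  den <- comp$a + comp$b + comp$c
  usable <- fa$n >= 1 & fb$n >= 1 & !is.na(den)
  map <- site_window_map(windows, gm$sites$chrom[usable],
                         gm$sites$pos[usable] - 1L)
  num_sum <- rep(0, nrow(windows))
  den_sum <- rep(0, nrow(windows))
  n_var <- rep(0L, nrow(windows))
  if (nrow(map) > 0) {
    add <- function(x) as.numeric(tapply(x[usable][map$site], map$window, sum))
    wid <- as.integer(names(tapply(map$site, map$window, length)))
    num_sum[wid] <- add(num)
    den_sum[wid] <- add(den)
    n_var[wid] <- as.integer(tapply(map$site, map$window, length))
  }
  windows |>
    mutate(n_variants = n_var,
           fst = ifelse(n_var > 0 & den_sum > 0, num_sum / den_sum, NA_real_),
           excluded = n_var == 0 | den_sum <= 0)
}

#' Per-site Weir-Cockerham FST (diagnostic)
#'
#' @inheritParams windowed_fst
#' @return A tibble `chrom`, `pos`, `a`, `b`, `c`, `fst`.
#' @export
site_fst <- function(gm, pop_a, pop_b) {
  fa <- pop_site_freq(gm, pop_a)
  fb <- pop_site_freq(gm, pop_b)
  comp <- fst_components(fa$p, fb$p, fa$h, fb$h, fa$n, fb$n)
  den <- comp$a + comp$b + comp$c
  tibble(chrom = gm$sites$chrom, pos = gm$sites$pos,
         a = comp$a, b = comp$b, c = comp$c,
         fst = ifelse(!is.na(den) & den > 0, comp$a / den, NA_real_))
}
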