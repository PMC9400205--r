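#' Median over usable windows
#'
#' The genome-wide summary used for reporting per-population diversity
#' and per-contrast differentiation: the standard median (mean of the
#' central pair for even counts) over windows not flagged excluded/empty.
#'
#' @param values Numeric vector of per-window statistics; `NA` = excluded.
#' @return The median.
#' @export
median_stat <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) == 0) abort("no usable windows to summarise")
  median(v)
}

#' Compare two window-statistic distributions (Wilcoxon rank-sum)
#'
#' Two-sided Mann-Whitney test with the normal approximation and tie
#' correction, as used to compare genome-wide FST distributions between
#' population contrasts.
#'
#' @param values_a,values_b Numeric vectors (NAs dropped).
#' @return A tibble with `statistic` (the Mann-Whitney U for the first
#'   sample), `p_value`, `n_a`, `n_b`.
#' @export
compare_distributions <- function(values_a, values_b) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) == 0 || length(b) == 0) abort("both samples must be non-empty")
  wt <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
         n_a = length(a), n_b = length(b))
}
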