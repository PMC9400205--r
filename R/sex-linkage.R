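#' Sex-scan parameters
#'
#' Classification bands on the chromosome-level median `m` of per-window
#' `log2(F:M)` coverage ratios: autosome `|m| <= autosome_halfwidth`,
#' X-linked `|m - 1| <= x_halfwidth`, Y-linked `m <= y_max`, otherwise
#' undetermined. The half-widths (default 0.35) separate the expected
#' modes at 0 and 1 symmetrically while tolerating Poisson depth noise at
#' >= 10x coverage; the Y rule is the literal `<= -1` cut. `pseudocount`
#' keeps the log ratio finite when a sex group has zero depth (e.g.
#' females on Y); `min_male_depth` flags windows with negligible male
#' coverage as unusable.
#'
#' @param pseudocount Positive depth offset added to both group means.
#' @param min_male_depth Windows with male mean depth below this are
#'   unusable.
#' @param autosome_halfwidth,x_halfwidth Band half-widths around 0 and 1.
#' @param y_max Upper bound of the Y band.
#' @param min_windows Minimum usable windows for a chromosome-level call.
#' @return A list of class `sex_scan_params`.
#' @export
sex_scan_params <- function(pseudocount = 0.1, min_male_depth = 1.0,
                            autosome_halfwidth = 0.35, x_halfwidth = 0.35,
                            y_max = -1, min_windows = 10) {
  stopifnot(pseudocount > 0,
            # bands must not overlap
            y_max < -autosome_halfwidth,
            autosome_halfwidth < 1 - x_halfwidth)
  structure(list(pseudocount = pseudocount, min_male_depth = min_male_depth,
                 autosome_halfwidth = autosome_halfwidth,
                 x_halfwidth = x_halfwidth, y_max = y_max,
                 min_windows = min_windows),
            class = "sex_scan_params")
}

#' Per-window mean coverage by sex group
#'
#' @param coverage A coverage tibble from [read_coverage()] or
#'   [simulate_coverage()].
#' @param meta Sample metadata with `sample` and `sex`; unknown-sex
#'   samples are ignored.
#' @return A tibble `chrom`, `start`, `end`, `f_mean`, `m_mean`.
#' @export
group_mean_coverage <- function(coverage, meta) {
  samples <- setdiff(names(coverage), c("chrom", "start", "end"))
  f_ids <- intersect(meta$sample[meta$sex == "F"], samples)
  m_ids <- intersect(meta$sample[meta$sex == "M"], samples)
  if (length(f_ids) == 0 || length(m_ids) == 0) {
    abort("need at least one female and one male sample with coverage")
  }
  tibble(
    chrom = coverage$chrom, start = coverage$start, end = coverage$end,
    f_mean = rowMeans(as.matrix(coverage[f_ids])),
    m_mean = rowMeans(as.matrix(coverage[m_ids]))
  )
}

#' Per-window log2 female:male coverage ratio
#'
#' `log2((F + delta) / (M + delta))`. Windows whose male mean depth falls
#' below `min_male_depth` are marked unusable (ratios there are dominated
#' by the pseudocount, not biology).
#'
#' @param group_means Tibble from [group_mean_coverage()].
#' @param params A [sex_scan_params()].
#' @return The input with `log2_ratio` and `usable` columns added.
#' @export
fm_log_ratio <- function(group_means, params = sex_scan_params()) {
  d <- params$pseudocount
  group_means |>
    mutate(log2_ratio = log2((.data$f_mean + d) / (.data$m_mean + d)),
           usable = .data$m_mean >= params$min_male_depth)
}

#' Classify chromosomes as autosome / X / Y from coverage ratios
#'
#' The chromosome-level statistic is the median `log2(F:M)` over usable
#' windows (robust to mismapped windows); chromosomes with fewer than
#' `min_windows` usable windows are undetermined.
#'
#' @param coverage Coverage tibble (`chrom`, `start`, `end`, one column
#'   per sample).
#' @param meta Sample metadata (`sample`, `sex`).
#' @param params A [sex_scan_params()].
#' @return A list of class `sex_scan`: `calls` (tibble `chrom`,
#'   `median_log2_ratio`, `n_windows`, `call`) and `windows` (per-window
#'   table with `log2_ratio`, the boxplot/scatter substrate).
#' @export
classify_chromosomes <- function(coverage, meta, params = sex_scan_params()) {
  gw <- group_mean_coverage(coverage, meta)
  gw <- fm_log_ratio(gw, params)
  calls <- gw |>
    filter(.data$usable) |>
    group_by(.data$chrom) |>
    summarise(median_log2_ratio = median(.data$log2_ratio),
              n_windows = n(), .groups = "drop") |>
    mutate(call = classify_band(.data$median_log2_ratio, .data$n_windows,
                                params))
  # chromosomes with no usable window at all
  absent <- setdiff(unique(gw$chrom), calls$chrom)
  if (length(absent) > 0) {
    calls <- bind_rows(calls, tibble(
      chrom = absent, median_log2_ratio = NA_real_, n_windows = 0L,
      call = "undetermined"))
  }
  structure(list(calls = arrange(calls, .data$chrom), windows = gw,
                 params = params),
            class = "sex_scan")
}

classify_band <- function(m, n_windows, params) {
  dplyr::case_when(
    n_windows < params$min_windows ~ "undetermined",
    m <= params$y_max ~ "Y-linked",
    abs(m) <= params$autosome_halfwidth ~ "autosome",
    abs(m - 1) <= params$x_halfwidth ~ "X-linked",
    .default = "undetermined"
  )
}

#' @export
print.sex_scan <- function(x, ...) {
  cat("<sex_scan>\n")
  print(x$calls, n = 20)
  invisible(x)
}

#' @method tidy sex_scan
#' @export
tidy.sex_scan <- function(x, ...) x$calls

#' @method glance sex_scan
#' @export
glance.sex_scan <- function(x, ...) {
  tibble(
    n_chromosomes = nrow(x$calls),
    n_autosome = sum(x$calls$call == "autosome"),
    n_x = sum(x$calls$call == "X-linked"),
    n_y = sum(x$calls$call == "Y-linked"),
    n_undetermined = sum(x$calls$call == "undetermined")
  )
}
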