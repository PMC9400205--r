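#' Manhattan-style plot of windowed FST
#'
#' @param ws A [window_stats()] tibble.
#' @param contrast `c(reference, target)` population labels.
#' @param q Quantile line to draw (default 0.95).
#' @return A ggplot.
#' @export
plot_fst_manhattan <- function(ws, contrast, q = 0.95) {
  col <- paste0("fst_", contrast[1], "_", contrast[2])
  if (!col %in% names(ws)) abort(paste0("no column ", col))
  df <- as_tibble(ws) |>
    mutate(mid = (.data$start + .data$end) / 2, fst = .data[[col]]) |>
    filter(!is.na(.data$fst))
  thr <- sort(df$fst)[ceiling(q * nrow(df))]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$fst)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = thr, colour = "red",
                        linetype = "dashed") +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (bp)",
                  y = expression(F[ST]),
                  title = paste(contrast[1], "vs", contrast[2])) +
    ggplot2::theme_minimal()
}

#' Windowed sweep-scan overview
#'
#' FST against diversity ratio per window with the two outlier cutoffs;
#' candidate windows (upper-right intersection) highlighted.
#'
#' @param object A [sweep_scan()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sweep_scan
#' @export
autoplot.sweep_scan <- function(object, ...) {
  w <- object$windows |>
    filter(!is.na(.data$fst) & !is.na(.data$pi_ratio))
  ggplot2::ggplot(w, ggplot2::aes(x = .data$fst, y = .data$pi_ratio,
                                  colour = .data$candidate)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = expression(F[ST]),
                  y = expression(pi[ref] / pi[target]),
                  colour = "candidate") +
    ggplot2::theme_minimal()
}

#' Per-chromosome log2 coverage-ratio boxplot
#'
#' @param object A [classify_chromosomes()] result.
#' @param ... Unused.
#' @return A ggplot with the autosome/X/Y reference lines at 0, 1, -1.
#' @method autoplot sex_scan
#' @export
autoplot.sex_scan <- function(object, ...) {
  w <- object$windows |> filter(.data$usable)
  ggplot2::ggplot(w, ggplot2::aes(x = .data$chrom, y = .data$log2_ratio)) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::geom_hline(yintercept = c(0, 1, -1), linetype = "dotted",
                        colour = c("grey30", "blue", "red")) +
    ggplot2::labs(x = NULL, y = expression(log[2](F:M))) +
    ggplot2::theme_minimal()
}

#' PCA scatter of the first two components
#'
#' @param object A [pca_genotypes()] result.
#' @param meta Optional metadata tibble to colour by population.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pca_result
#' @export
autoplot.pca_result <- function(object, meta = NULL, ...) {
  df <- object$coordinates
  if (!is.null(meta)) {
    df <- left_join(df, meta, by = "sample")
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                          colour = .data$population))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  }
  p + ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])) +
    ggplot2::theme_minimal()
}

#' Windowed diversity track per population
#'
#' @param ws A [window_stats()] tibble.
#' @return A ggplot of per-window diversity, one facet per chromosome.
#' @export
plot_pi_track <- function(ws) {
  pi_cols <- grep("^pi_", names(ws), value = TRUE)
  df <- as_tibble(ws) |>
    tidyr::pivot_longer(all_of(pi_cols), names_to = "population",
                        values_to = "pi", names_prefix = "pi_") |>
    filter(!is.na(.data$pi)) |>
    mutate(mid = (.data$start + .data$end) / 2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$pi,
                                   colour = .data$population)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (bp)", y = expression(pi ~ "(per bp)")) +
    ggplot2::theme_minimal()
}
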