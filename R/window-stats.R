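#' Per-window diversity and differentiation table
#'
#' Builds the central window table: per-population per-bp nucleotide
#' diversity and weighted Weir-Cockerham FST for each requested contrast,
#' on a shared sliding-window grid.
#'
#' @param gm A filtered [genotype_matrix()].
#' @param meta Sample-metadata tibble (see [read_sample_metadata()]).
#' @param spec A [window_spec()].
#' @param contrasts List of 2-vectors `c(reference, target)` of population
#'   labels; default: no FST columns.
#' @param populations Populations to compute diversity for; default all in
#'   `meta` that have samples in `gm`.
#' @return A tibble of class `window_stats`: `chrom`, `start`, `end`
#'   (0-based half-open), `n_variants`, one `pi_<pop>` column per
#'   population and one `fst_<ref>_<target>` column per contrast. Windows
#'   unusable for a statistic hold `NA`.
#' @export
window_stats <- function(gm, meta, spec, contrasts = list(),
                         populations = NULL) {
  pops <- split(meta$sample, meta$population)
  pops <- lapply(pops, intersect, y = sample_ids(gm))
  if (is.null(populations)) {
    populations <- names(pops)[lengths(pops) > 0]
  }
  missing_pop <- setdiff(
    unique(c(populations, unlist(contrasts))), names(pops)
  )
  if (length(missing_pop) > 0) {
    abort(paste0("populations absent from metadata: ",
                 paste(missing_pop, collapse = ", ")))
  }

  out <- NULL
  for (pop in populations) {
    wp <- windowed_pi(gm, pops[[pop]], spec)
    col <- paste0("pi_", pop)
    if (is.null(out)) {
      out <- wp |> select("chrom", "start", "end", "n_variants")
    }
    out[[col]] <- wp$pi
  }
  if (is.null(out)) {
    out <- make_all_windows(spec) |> mutate(n_variants = NA_integer_)
  }
  for (ct in contrasts) {
    wf <- windowed_fst(gm, pops[[ct[1]]], pops[[ct[2]]], spec)
    out[[paste0("fst_", ct[1], "_", ct[2])]] <- wf$fst
  }
  class(out) <- c("window_stats", class(out))
  out
}

#' Write a window-statistics table as TSV
#'
#' Output coordinates are converted to the 1-based inclusive
#' `BIN_START`/`BIN_END` dialect of the usual windowed-statistics tools.
#'
#' @param ws A [window_stats()] tibble.
#' @param path Output path.
#' @param comment Optional provenance comment lines.
#' @return `path`, invisibly.
#' @export
write_window_stats <- function(ws, path, comment = NULL) {
  out <- ws |>
    mutate(BIN_START = .data$start + 1L, BIN_END = .data$end) |>
    select(CHROM = "chrom", "BIN_START", "BIN_END",
           N_VARIANTS = "n_variants", dplyr::starts_with("pi_"),
           dplyr::starts_with("fst_"))
  names(out) <- sub("^pi_", "PI_", names(out))
  names(out) <- sub("^fst_", "WEIGHTED_FST_", names(out))
  write_tsv_commented(out, path, comment)
}
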