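#' Sliding-window specification
#'
#' Windows of `size_bp` advanced by `step_bp` (default 5 kb / 2.5 kb, the
#' usual windowed-FST configuration). Starts are `0, step, 2*step, ...`
#' while `start < chrom length`; the last window is truncated at the
#' chromosome end. Coordinates are 0-based half-open.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param size_bp Window size in bp.
#' @param step_bp Step between window starts in bp; `0 < step <= size`.
#' @return A list of class `window_spec`.
#' @export
window_spec <- function(chrom_lengths, size_bp = 5000, step_bp = 2500) {
  stopifnot(step_bp > 0, step_bp <= size_bp,
            !is.null(names(chrom_lengths)), all(chrom_lengths >= 0))
  structure(list(chrom_lengths = chrom_lengths,
                 size_bp = as.integer(size_bp),
                 step_bp = as.integer(step_bp)),
            class = "window_spec")
}

#' Enumerate the windows of one chromosome
#'
#' @param spec A [window_spec()].
#' @param chrom Chromosome name (must be in `spec`).
#' @return A tibble `chrom`, `start`, `end` (0-based half-open), ordered.
#' @export
make_windows <- function(spec, chrom) {
  if (!chrom %in% names(spec$chrom_lengths)) {
    abort(paste0("unknown chromosome: ", chrom))
  }
  len <- as.integer(spec$chrom_lengths[[chrom]])
  if (len == 0) {
    return(tibble(chrom = chrom[0], start = integer(), end = integer()))
  }
  # every full window, plus at most one truncated terminal window
  starts <- seq(0L, len - 1L, by = spec$step_bp)
  full <- starts + spec$size_bp <= len
  if (any(!full)) starts <- starts[seq_len(sum(full) + 1L)]
  tibble(chrom = chrom, start = starts,
         end = pmin(starts + spec$size_bp, len))
}

#' All windows of all chromosomes
#' @rdname make_windows
#' @export
make_all_windows <- function(spec) {
  purrr::map(names(spec$chrom_lengths), function(ch) make_windows(spec, ch)) |>
    bind_rows()
}

# For each (chrom, 0-based pos) return the indices of every window row
# containing it. With step <= size a site falls into at most
# ceiling(size/step) windows; returns a tibble (site, window).
site_window_map <- function(windows, chrom, pos0) {
  out <- vector("list", 0)
  idx_by_chrom <- split(seq_len(nrow(windows)), windows$chrom)
  site_by_chrom <- split(seq_along(pos0), chrom)
  for (ch in names(site_by_chrom)) {
    wi <- idx_by_chrom[[ch]]
    if (is.null(wi)) next
    w <- windows[wi, ]
    si <- site_by_chrom[[ch]]
    p <- pos0[si]
    step <- if (nrow(w) > 1) w$start[2] - w$start[1] else max(w$end)
    max_span <- ceiling(max(w$end - w$start) / step)
    # candidate window k has start index floor(p/step) - j, j = 0..span-1
    base <- p %/% step
    for (j in 0:(max_span - 1)) {
      k <- base - j + 1L
      ok <- k >= 1 & k <= nrow(w)
      kk <- k[ok]
      pp <- p[ok]
      ss <- si[ok]
      inside <- pp >= w$start[kk] & pp < w$end[kk]
      if (any(inside)) {
        out[[length(out) + 1]] <- tibble(site = ss[inside],
                                         window = wi[kk[inside]])
      }
    }
  }
  if (length(out) == 0) return(tibble(site = integer(), window = integer()))
  bind_rows(out)
}
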