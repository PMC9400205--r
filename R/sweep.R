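#' Between-population diversity ratio per window
#'
#' \deqn{\rho_w = (\pi_{ref,w} + \epsilon) / (\pi_{target,w} + \epsilon)}
#' Oriented so that a sweep in the *target* population (local diversity
#' loss) gives a large ratio. The pseudocount keeps zero-diversity
#' windows finite without disturbing the ranking (default 1e-5, below any
#' plausible per-bp diversity). Windows empty in either population are
#' excluded (`NA`).
#'
#' @param pi_ref,pi_target Aligned per-window diversity vectors
#'   (`NA` = empty window).
#' @param epsilon Positive pseudocount.
#' @return Numeric vector of ratios, `NA` where excluded.
#' @export
pi_ratio <- function(pi_ref, pi_target, epsilon = 1e-5) {
  if (length(pi_ref) != length(pi_target)) abort("window lists not aligned")
  if (epsilon <= 0) abort("epsilon must be positive")
  (pi_ref + epsilon) / (pi_target + epsilon)
}

#' Upper-quantile outlier mask
#'
#' The threshold is the `ceiling(q * W)`-th order statistic of the `W`
#' usable values; values strictly greater are flagged. With distinct
#' values and `W` divisible by `1/(1-q)` this flags exactly a `1 - q`
#' fraction; ties at the threshold are never flagged, so the flagged
#' fraction never exceeds `1 - q`.
#'
#' @param values Numeric vector (`NA` = excluded, never flagged).
#' @param q Quantile in (0, 1), default 0.95.
#' @return Logical mask aligned with `values`.
#' @export
quantile_outliers <- function(values, q = 0.95) {
  stopifnot(q > 0, q < 1)
  v <- values[!is.na(values)]
  if (length(v) < 1 / (1 - q)) {
    abort(sprintf(
      "only %d usable windows: need at least %d for q = %g (use more data)",
      length(v), ceiling(1 / (1 - q)), q))
  }
  thr <- sort(v)[ceiling(q * length(v))]
  !is.na(values) & values > thr
}

#' Intersection of outlier masks
#'
#' Candidate sweep windows are outliers on *both* differentiation and
#' diversity ratio. Windows excluded (NA) from either statistic are
#' excluded entirely.
#'
#' @param fst_mask,ratio_mask Aligned logical masks (`NA` = excluded).
#' @return Logical mask; `FALSE` wherever either input is `NA`.
#' @export
intersect_outliers <- function(fst_mask, ratio_mask) {
  if (length(fst_mask) != length(ratio_mask)) abort("mask length mismatch")
  out <- fst_mask & ratio_mask
  out[is.na(out)] <- FALSE
  out
}

#' Merge flagged windows into candidate sweep regions
#'
#' Overlapping or book-ended flagged windows on one chromosome are merged
#' into maximal intervals; per-region peak statistics are the maxima over
#' member windows.
#'
#' @param windows A window tibble (`chrom`, `start`, `end`, plus any
#'   per-window statistic columns, e.g. `fst`, `pi_ratio`).
#' @param flagged Logical mask over rows of `windows`.
#' @return A tibble of regions: `chrom`, `start`, `end`, `n_windows`,
#'   `peak_<stat>` for each numeric statistic column present.
#' @export
merge_regions <- function(windows, flagged) {
  stopifnot(nrow(windows) == length(flagged))
  w <- windows[which(flagged), , drop = FALSE]
  if (nrow(w) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  n_windows = integer()))
  }
  stat_cols <- setdiff(names(w)[vapply(w, is.numeric, logical(1))],
                       c("start", "end", "n_variants"))
  out <- lapply(split(w, w$chrom), function(ch) {
    ch <- arrange(ch, .data$start)
    ir <- IRanges::IRanges(start = ch$start + 1L, end = ch$end)  # 1-based closed
    red <- IRanges::reduce(ir)  # merges overlapping and book-ended runs
    hit <- IRanges::findOverlaps(ir, red)
    grp <- S4Vectors::subjectHits(hit)
    res <- tibble(chrom = ch$chrom[1],
                  start = IRanges::start(red) - 1L,
                  end = IRanges::end(red),
                  n_windows = as.integer(table(grp)))
    for (sc in stat_cols) {
      res[[paste0("peak_", sc)]] <-
        as.numeric(tapply(ch[[sc]], grp, max, na.rm = TRUE))
    }
    res
  })
  bind_rows(out) |> arrange(.data$chrom, .data$start)
}

#' Annotate regions with overlapping genes
#'
#' A gene is assigned to a region iff they share at least one bp
#' (half-open arithmetic). Also returns the deduplicated swept-gene list.
#'
#' @param regions Region tibble (`chrom`, `start`, `end`, 0-based
#'   half-open).
#' @param genes Gene-interval tibble from [read_intervals()].
#' @return A list: `regions` (input plus a `gene_ids` list-column and
#'   `n_genes`), `genes` (character vector of unique overlapping gene
#'   ids).
#' @export
overlap_genes <- function(regions, genes) {
  if (nrow(regions) == 0) {
    regions$gene_ids <- list()
    regions$n_genes <- integer()
    return(list(regions = regions, genes = character()))
  }
  hits <- vector("list", nrow(regions))
  for (ch in unique(regions$chrom)) {
    ri <- which(regions$chrom == ch)
    gi <- which(genes$chrom == ch)
    if (length(gi) == 0) { hits[ri] <- list(character()); next }
    ir_r <- IRanges::IRanges(regions$start[ri] + 1L, regions$end[ri])
    ir_g <- IRanges::IRanges(genes$start[gi] + 1L, genes$end[gi])
    ov <- IRanges::findOverlaps(ir_r, ir_g)
    for (k in seq_along(ri)) {
      hits[[ri[k]]] <-
        genes$gene_id[gi[S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == k]]]
    }
  }
  regions$gene_ids <- hits
  regions$n_genes <- lengths(hits)
  list(regions = regions, genes = unique(unlist(hits)))
}

#' Candidate selective-sweep scan
#'
#' The full caller: computes the diversity ratio, flags the upper-`q`
#' outliers of the FST and ratio distributions, intersects the two masks,
#' merges flagged windows into regions and (optionally) annotates
#' overlapping genes.
#'
#' @param ws A [window_stats()] tibble.
#' @param ref_pop,target_pop Population labels; the target is the
#'   population scanned for sweeps (diversity loss).
#' @param q Upper quantile (default 0.95).
#' @param epsilon Diversity-ratio pseudocount.
#' @param genes Optional gene-interval tibble.
#' @return A list of class `sweep_scan`: `windows` (the input windows
#'   plus `pi_ratio`, `fst_outlier`, `ratio_outlier`, `candidate`),
#'   `regions`, `genes`, and the scan parameters.
#' @export
sweep_scan <- function(ws, ref_pop, target_pop, q = 0.95, epsilon = 1e-5,
                       genes = NULL) {
  fst_col <- paste0("fst_", ref_pop, "_", target_pop)
  if (!fst_col %in% names(ws)) {
    # contrast may have been computed in the other orientation
    alt <- paste0("fst_", target_pop, "_", ref_pop)
    if (!alt %in% names(ws)) {
      abort(paste0("window table lacks an FST column for contrast ",
                   ref_pop, " vs ", target_pop))
    }
    fst_col <- alt
  }
  pi_ref <- ws[[paste0("pi_", ref_pop)]]
  pi_tgt <- ws[[paste0("pi_", target_pop)]]
  if (is.null(pi_ref) || is.null(pi_tgt)) {
    abort("window table lacks diversity columns for the two populations")
  }
  w <- as_tibble(ws)
  w$fst <- w[[fst_col]]
  w$pi_ratio <- pi_ratio(pi_ref, pi_tgt, epsilon)
  usable <- !is.na(w$fst) & !is.na(w$pi_ratio)
  fst_v <- ifelse(usable, w$fst, NA_real_)
  rho_v <- ifelse(usable, w$pi_ratio, NA_real_)
  w$fst_outlier <- quantile_outliers(fst_v, q)
  w$ratio_outlier <- quantile_outliers(rho_v, q)
  w$candidate <- intersect_outliers(w$fst_outlier, w$ratio_outlier)
  regions <- merge_regions(
    w |> select("chrom", "start", "end", "fst", "pi_ratio"),
    w$candidate
  )
  gene_list <- character()
  if (!is.null(genes)) {
    og <- overlap_genes(regions, genes)
    regions <- og$regions
    gene_list <- og$genes
  }
  structure(
    list(windows = w, regions = regions, genes = gene_list,
         params = list(ref_pop = ref_pop, target_pop = target_pop,
                       q = q, epsilon = epsilon)),
    class = "sweep_scan"
  )
}

#' @export
print.sweep_scan <- function(x, ...) {
  cat(sprintf(
    "<sweep_scan> %s (reference) vs %s (target), q = %g\n",
    x$params$ref_pop, x$params$target_pop, x$params$q))
  cat(sprintf("  %d candidate windows -> %d merged regions, %d genes\n",
              sum(x$windows$candidate), nrow(x$regions), length(x$genes)))
  invisible(x)
}

#' @method tidy sweep_scan
#' @export
tidy.sweep_scan <- function(x, ...) {
  regions <- x$regions
  if (nrow(regions) > 0 && "gene_ids" %in% names(regions)) {
    regions$gene_ids <- vapply(regions$gene_ids, paste, character(1),
                               collapse = ",")
  }
  as_tibble(regions)
}

#' @method glance sweep_scan
#' @export
glance.sweep_scan <- function(x, ...) {
  tibble(
    ref_pop = x$params$ref_pop, target_pop = x$params$target_pop,
    q = x$params$q,
    n_windows_usable = sum(!is.na(x$windows$fst) & !is.na(x$windows$pi_ratio)),
    n_candidate_windows = sum(x$windows$candidate),
    n_regions = nrow(x$regions),
    n_genes = length(x$genes)
  )
}
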