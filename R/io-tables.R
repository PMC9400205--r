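#' Read sample metadata (sample, population, sex)
#'
#' @param path TSV with columns `sample`, `population`, `sex`. Sex labels
#'   are normalised case-insensitively: `F`/`female` -> `"F"`,
#'   `M`/`male` -> `"M"`, anything else (including empty) -> `"unknown"`.
#' @return A tibble with columns `sample`, `population`, `sex`.
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  req <- c("sample", "population", "sex")
  if (!all(req %in% names(meta))) {
    abort("metadata must have columns sample, population, sex")
  }
  if (anyDuplicated(meta$sample)) {
    dup <- meta$sample[duplicated(meta$sample)][1]
    abort(paste0("duplicate sample id in metadata: ", dup))
  }
  if (any(is.na(meta$population) | meta$population == "")) {
    abort("population labels must be non-empty")
  }
  meta |>
    mutate(sex = normalise_sex(.data$sex)) |>
    select(all_of(req))
}

normalise_sex <- function(x) {
  x <- toupper(trimws(ifelse(is.na(x), "", x)))
  dplyr::case_when(
    x %in% c("F", "FEMALE") ~ "F",
    x %in% c("M", "MALE") ~ "M",
    .default = "unknown"
  )
}

#' Read gene intervals from BED or GFF3
#'
#' Intervals are normalised to the package-wide 0-based half-open
#' convention: BED coordinates pass through unchanged; GFF3 1-based
#' inclusive coordinates become `[start - 1, end)`. Only `type == "gene"`
#' rows of a GFF3 are kept, identified by their `ID` (or `Name`)
#' attribute.
#'
#' @param path Path to the annotation file.
#' @param format `"bed"` or `"gff3"`; default guesses from the extension.
#' @return A tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `gene_id`.
#' @export
read_intervals <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
      "gff3" else "bed"
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  if (format == "gff3") {
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
    ids <- as.character(gr$ID)
    if (all(is.na(ids)) && !is.null(gr$Name)) ids <- as.character(gr$Name)
  } else {
    ids <- if (!is.null(gr$name)) as.character(gr$name) else
      paste0("interval_", seq_along(gr))
  }
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # back to 0-based half-open
    end = GenomicRanges::end(gr),
    gene_id = ids
  )
  if (any(is.na(out$gene_id) | out$gene_id == "")) {
    abort("every gene interval needs a non-empty id")
  }
  if (any(out$start >= out$end)) abort("interval with start >= end")
  arrange(out, .data$chrom, .data$start)
}

#' Read a per-window coverage track
#'
#' @param path TSV with columns `chrom`, `start`, `end` (0-based
#'   half-open, fixed-width windows tiling each chromosome) followed by
#'   one depth column per sample.
#' @return A tibble (class `coverage_track`) with the same columns; the
#'   window width is stored in attribute `window_size`.
#' @export
read_coverage <- function(path) {
  cov <- readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", start = "i", end = "i", .default = "d"
  ))
  validate_coverage(cov)
}

validate_coverage <- function(cov) {
  stopifnot(all(c("chrom", "start", "end") %in% names(cov)))
  samples <- setdiff(names(cov), c("chrom", "start", "end"))
  if (length(samples) == 0) abort("coverage table has no sample columns")
  widths <- cov$end - cov$start
  if (length(unique(widths)) > 1) {
    abort("coverage windows must have a single fixed width")
  }
  by_chrom <- split(cov, cov$chrom)
  for (ch in by_chrom) {
    ch <- arrange(ch, .data$start)
    if (nrow(ch) > 1 && any(ch$start[-1] != ch$end[-nrow(ch)])) {
      abort("coverage windows must tile each chromosome without gaps or overlap")
    }
  }
  depth <- as.matrix(cov[samples])
  if (any(depth < 0, na.rm = TRUE)) abort("negative depth in coverage track")
  out <- as_tibble(cov)
  class(out) <- c("coverage_track", class(out))
  attr(out, "window_size") <- unique(widths)
  out
}

#' Write tables emitted by the pipeline
#'
#' Thin TSV writers for the simulator and pipeline outputs. Window and
#' region tables are written with 1-based inclusive coordinates (the
#' dialect of the usual windowed-statistics tools); in-memory objects stay
#' 0-based half-open.
#'
#' @param x Tibble to write.
#' @param path Output path.
#' @param comment Optional `#`-prefixed header lines (provenance).
#' @return `path`, invisibly.
#' @export
write_tsv_commented <- function(x, path, comment = NULL) {
  if (!is.null(comment)) {
    writeLines(paste0("# ", comment), path)
    readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(x, path)
  }
  invisible(path)
}
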