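#' Genotype dosage matrix
#'
#' The central container for SNP genotypes: a sites-by-samples matrix of
#' alternate-allele dosages (0, 1, 2 or `NA` for missing) together with
#' per-site metadata (chromosome, 1-based position, REF and ALT alleles).
#' All downstream statistics (diversity, FST, distances, PCA) consume this
#' object. Internally the package works in 0-based half-open coordinates;
#' `pos` here is the 1-based VCF position and is converted at window
#' boundaries.
#'
#' @param sites A data frame with columns `chrom`, `pos` (1-based integer),
#'   `ref`, `alt`. `alt` may hold comma-separated alternates for
#'   multi-allelic records (removed later by [biallelic_filter()]).
#' @param dosage Integer matrix, one row per site, one column per sample,
#'   values in `{0, 1, 2, NA}`. Column names are sample ids.
#' @param gq Optional integer matrix of genotype qualities, same shape as
#'   `dosage`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `sites` (tibble), `dosage` (integer matrix), `gq` (matrix or `NULL`).
#' @examples
#' gm <- genotype_matrix(
#'   sites = data.frame(chrom = "chr1", pos = c(100L, 200L),
#'                      ref = c("A", "C"), alt = c("G", "T")),
#'   dosage = matrix(c(0L, 1L, 2L, NA), 2, 2,
#'                   dimnames = list(NULL, c("S1", "S2")))
#' )
#' gm
#' @export
genotype_matrix <- function(sites, dosage, gq = NULL) {
  sites <- as_tibble(sites)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  dosage <- as.matrix(dosage)
  if (nrow(dosage) != nrow(sites)) {
    abort("`dosage` must have one row per site.")
  }
  if (is.null(colnames(dosage))) {
    abort("`dosage` must carry sample ids as column names.")
  }
  bad <- !(dosage %in% c(0L, 1L, 2L, NA))
  if (any(bad)) abort("dosage values must be 0, 1, 2 or NA.")
  storage.mode(dosage) <- "integer"
  sites$pos <- as.integer(sites$pos)
  # positions strictly increasing within each chromosome
  by_chrom <- split(sites$pos, sites$chrom)
  if (any(vapply(by_chrom, function(p) any(diff(p) <= 0), logical(1)))) {
    abort("positions must be strictly increasing within each chromosome.")
  }
  if (!is.null(gq)) {
    gq <- as.matrix(gq)
    stopifnot(identical(dim(gq), dim(dosage)))
  }
  structure(list(sites = sites, dosage = dosage, gq = gq),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d sites x %d samples on %d chromosome(s)\n",
    n_sites(x), n_samples(x), length(unique(x$sites$chrom))
  ))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing genotypes: %.2f%%; GQ: %s\n",
              100 * miss, if (is.null(x$gq)) "absent" else "present"))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param x,gm A `genotype_matrix`.
#' @export
n_sites <- function(gm) nrow(gm$sites)

#' @rdname genotype_matrix
#' @export
n_samples <- function(gm) ncol(gm$dosage)

#' @rdname genotype_matrix
#' @export
sample_ids <- function(gm) colnames(gm$dosage)

#' Subset a genotype matrix by sites and/or samples
#'
#' @param gm A [genotype_matrix()].
#' @param sites Logical or integer index over sites.
#' @param samples Character vector of sample ids, or index over columns.
#' @return A `genotype_matrix` restricted to the selection.
#' @export
subset_gm <- function(gm, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_len(n_sites(gm))
  if (is.null(samples)) samples <- seq_len(n_samples(gm))
  genotype_matrix(
    sites = gm$sites[sites, , drop = FALSE],
    dosage = gm$dosage[sites, samples, drop = FALSE],
    gq = if (!is.null(gm$gq)) gm$gq[sites, samples, drop = FALSE]
  )
}

#' Tidy a genotype matrix into a long tibble
#'
#' @param x A [genotype_matrix()].
#' @param ... Unused.
#' @return A tibble with one row per site x sample: `chrom`, `pos`,
#'   `sample`, `dosage` (and `gq` when present).
#' @method tidy genotype_matrix
#' @export
tidy.genotype_matrix <- function(x, ...) {
  out <- tibble(
    chrom = rep(x$sites$chrom, times = n_samples(x)),
    pos = rep(x$sites$pos, times = n_samples(x)),
    sample = rep(sample_ids(x), each = n_sites(x)),
    dosage = as.vector(x$dosage)
  )
  if (!is.null(x$gq)) out$gq <- as.vector(x$gq)
  out
}

#' @method glance genotype_matrix
#' @export
glance.genotype_matrix <- function(x, ...) {
  tibble(
    n_sites = n_sites(x),
    n_samples = n_samples(x),
    n_chromosomes = length(unique(x$sites$chrom)),
    missing_rate = mean(is.na(x$dosage))
  )
}
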