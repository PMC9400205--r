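#' Read a multi-sample SNP VCF into a genotype matrix
#'
#' Parses a VCF v4.x file (plain or gzipped) and converts per-sample GT
#' fields into alternate-allele dosages: 0/0 -> 0, 0/1 -> 1, 1/1 -> 2,
#' ./. -> `NA`. Phasing is ignored (`|` treated as `/`). Multi-allelic
#' records are kept with their full ALT list so that the biallelic filter
#' can observe and remove them. The six GATK hard-filter INFO annotations
#' (QD, MQ, FS, SOR, MQRankSum, ReadPosRankSum) are extracted when present;
#' absent keys yield `NA` columns. Per-genotype GQ is extracted when the
#' FORMAT declares it.
#'
#' @param path Path to a VCF file.
#' @param region Optional region restriction, either `"chrom"` or
#'   `"chrom:start-end"` (1-based inclusive, as in tabix). A chromosome
#'   absent from the file yields an empty matrix, not an error.
#' @return A list with elements `gm` (a [genotype_matrix()]) and
#'   `annotations` (a tibble of per-site hard-filter annotations, aligned
#'   to the sites of `gm`).
#' @seealso [write_vcf()], [apply_all_filters()]
#' @export
read_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) abort(paste0("VCF not found: ", path))
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(paste0("failed to parse VCF '", path, "': ",
                                     conditionMessage(e)))
  )
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0) {
    samples <- if (ncol(vcf@gt) > 1) colnames(vcf@gt)[-1] else character()
    return(empty_vcf_result(samples))
  }
  sites <- tibble(
    chrom = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    ref = as.character(fix[, "REF"]),
    alt = as.character(fix[, "ALT"])
  )

  gt <- vcfR::extract.gt(vcf, element = "GT")
  dosage <- gt_to_dosage(gt)
  rownames(dosage) <- NULL

  gq <- NULL
  fmt <- vcf@gt[, "FORMAT"]
  if (any(grepl("(^|:)GQ(:|$)", fmt))) {
    gq <- suppressWarnings(vcfR::extract.gt(vcf, element = "GQ",
                                            as.numeric = TRUE))
    rownames(gq) <- NULL
  }

  ann_keys <- c("QD", "MQ", "FS", "SOR", "MQRankSum", "ReadPosRankSum")
  ann <- lapply(ann_keys, function(k) {
    suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = k)))
  })
  names(ann) <- ann_keys
  annotations <- as_tibble(ann)

  keep <- rep(TRUE, nrow(sites))
  if (!is.null(region)) {
    reg <- parse_region(region)
    keep <- sites$chrom == reg$chrom
    if (!is.null(reg$start)) {
      keep <- keep & sites$pos >= reg$start & sites$pos <= reg$end
    }
  }

  gm <- genotype_matrix(
    sites = sites[keep, , drop = FALSE],
    dosage = dosage[keep, , drop = FALSE],
    gq = if (!is.null(gq)) gq[keep, , drop = FALSE]
  )
  list(gm = gm, annotations = annotations[keep, , drop = FALSE])
}

empty_vcf_result <- function(samples) {
  gm <- genotype_matrix(
    sites = tibble(chrom = character(), pos = integer(),
                   ref = character(), alt = character()),
    dosage = matrix(integer(), nrow = 0, ncol = length(samples),
                    dimnames = list(NULL, samples))
  )
  ann <- as_tibble(setNames(
    rep(list(numeric()), 6),
    c("QD", "MQ", "FS", "SOR", "MQRankSum", "ReadPosRankSum")
  ))
  list(gm = gm, annotations = ann)
}

# "chr1" or "chr1:100-200" -> list(chrom, start, end)
parse_region <- function(region) {
  if (!grepl(":", region)) return(list(chrom = region, start = NULL, end = NULL))
  parts <- strsplit(region, "[:-]")[[1]]
  if (length(parts) != 3) abort("region must be 'chrom' or 'chrom:start-end'")
  list(chrom = parts[1], start = as.integer(parts[2]), end = as.integer(parts[3]))
}

# GT strings ("0/1", "1|1", "./.", ".") -> alt-allele dosage; any missing
# allele makes the cell missing.
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  lut <- vapply(u, function(g) {
    if (is.na(g)) return(NA_integer_)
    alleles <- strsplit(gsub("\\|", "/", g), "/", fixed = TRUE)[[1]]
    if (any(alleles == ".") || length(alleles) == 0) return(NA_integer_)
    sum(alleles != "0")
  }, integer(1))
  m <- matrix(lut[match(as.vector(gt), u)], nrow = nrow(gt),
              dimnames = dimnames(gt))
  storage.mode(m) <- "integer"
  m
}

#' Write a genotype matrix as a VCF v4.2 file
#'
#' Emits a plain-text VCF re-readable by [read_vcf()] with identical
#' chromosome, position, alleles and dosage. Dosages map to unphased GT
#' (0 -> 0/0, 1 -> 0/1, 2 -> 1/1, `NA` -> ./.); GQ is written as a second
#' FORMAT field when present.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  con <- tryCatch(file(path, "w"),
                  error = function(e) abort(paste0("cannot write: ", path)))
  on.exit(close(con))
  has_gq <- !is.null(gm$gq)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=invasweep",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (has_gq)
      '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype Quality">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids(gm)), collapse = "\t")
  )
  writeLines(header, con)
  if (n_sites(gm) > 0) {
    gt_codes <- c("0/0", "0/1", "1/1")
    gt <- matrix(gt_codes[gm$dosage + 1L], nrow = n_sites(gm))
    gt[is.na(gm$dosage)] <- "./."
    if (has_gq) {
      gqs <- ifelse(is.na(gm$gq), ".", as.character(gm$gq))
      gt <- matrix(paste(gt, gqs, sep = ":"), nrow = n_sites(gm))
      gt[is.na(gm$dosage) & is.na(gm$gq)] <- "./.:."
    }
    rec <- cbind(gm$sites$chrom, gm$sites$pos, ".", gm$sites$ref,
                 gm$sites$alt, ".", ".", ".",
                 if (has_gq) "GT:GQ" else "GT", gt)
    writeLines(apply(rec, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}
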