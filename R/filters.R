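#' Variant-site filter thresholds
#'
#' Defaults reproduce a conventional GATK-style short-variant filter set:
#' hard-filter cutoffs `QD < 2.0 || MQ < 40.0 || FS > 60.0 || SOR > 3.0 ||
#' MQRankSum < -12.5 || ReadPosRankSum < -8.0`, then biallelic-only,
#' genotype missing rate < 10%, minor allele frequency > 0.05 and exact
#' Hardy-Weinberg p >= 0.001. All inequalities are strict exactly as
#' written: a site at MQ = 40.0, missingness = 10% or MAF = 0.05 is on the
#' failing side of its rule. `gq_min` drives the optional genotype-quality
#' masking stage used before distance/PCA analyses (see [mask_low_gq()]).
#'
#' @param qd_min,mq_min,fs_max,sor_max,mqranksum_min,readposranksum_min
#'   Hard-filter cutoffs on the INFO annotations.
#' @param missing_max Maximum tolerated genotype missing fraction
#'   (exclusive bound).
#' @param maf_min Minimum minor allele frequency (exclusive bound).
#' @param hwe_alpha Sites with exact HWE p strictly below this are removed.
#' @param gq_min Genotype-quality cutoff for the optional masking stage.
#' @return A list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(qd_min = 2.0, mq_min = 40.0, fs_max = 60.0,
                              sor_max = 3.0, mqranksum_min = -12.5,
                              readposranksum_min = -8.0,
                              missing_max = 0.10, maf_min = 0.05,
                              hwe_alpha = 0.001, gq_min = 30) {
  t <- list(qd_min = qd_min, mq_min = mq_min, fs_max = fs_max,
            sor_max = sor_max, mqranksum_min = mqranksum_min,
            readposranksum_min = readposranksum_min,
            missing_max = missing_max, maf_min = maf_min,
            hwe_alpha = hwe_alpha, gq_min = gq_min)
  stopifnot(all(vapply(t, is.finite, logical(1))),
            missing_max >= 0, missing_max <= 1,
            maf_min >= 0, maf_min <= 0.5)
  structure(t, class = "filter_thresholds")
}

#' Hard-filter mask from INFO annotations
#'
#' A site fails if any *present* annotation violates its cutoff; missing
#' annotations never fail a site (un-annotatable sites, e.g. without a
#' heterozygous carrier for the rank-sum statistics, pass that clause).
#'
#' @param annotations Tibble with columns QD, MQ, FS, SOR, MQRankSum,
#'   ReadPosRankSum (any subset; `NA` = absent).
#' @param thresholds A [filter_thresholds()].
#' @return Logical vector, `TRUE` = site passes.
#' @export
hard_filter <- function(annotations, thresholds = filter_thresholds()) {
  t <- thresholds
  viol <- function(x, bad) !is.na(x) & bad(x)
  a <- annotations
  g <- function(k) if (k %in% names(a)) a[[k]] else rep(NA_real_, nrow(a))
  fails <- viol(g("QD"), function(x) x < t$qd_min) |
    viol(g("MQ"), function(x) x < t$mq_min) |
    viol(g("FS"), function(x) x > t$fs_max) |
    viol(g("SOR"), function(x) x > t$sor_max) |
    viol(g("MQRankSum"), function(x) x < t$mqranksum_min) |
    viol(g("ReadPosRankSum"), function(x) x < t$readposranksum_min)
  !fails
}

#' Biallelic-site mask
#'
#' Keeps sites whose ALT field is a single non-symbolic allele; records
#' with a second alternate or a spanning-deletion allele (`*`) are
#' removed.
#'
#' @param gm A [genotype_matrix()].
#' @return Logical vector, `TRUE` = site passes.
#' @export
biallelic_filter <- function(gm) {
  alt <- gm$sites$alt
  !grepl(",", alt, fixed = TRUE) & alt != "*" & alt != "" & !is.na(alt)
}

#' Missingness and minor-allele-frequency masks
#'
#' `missing fraction < missing_max` and `min(p, 1 - p) > maf_min`, with
#' the alternate-allele frequency `p` estimated over non-missing
#' genotypes. Both bounds are strict.
#'
#' @param gm A [genotype_matrix()].
#' @param samples Optional sample subset defining the analysis set.
#' @param thresholds A [filter_thresholds()].
#' @return A list of logical vectors `missing_ok`, `maf_ok`, `all_missing`.
#' @export
missingness_maf_filter <- function(gm, samples = NULL,
                                   thresholds = filter_thresholds()) {
  d <- if (is.null(samples)) gm$dosage else gm$dosage[, samples, drop = FALSE]
  n_tot <- ncol(d)
  n_called <- rowSums(!is.na(d))
  miss_frac <- (n_tot - n_called) / n_tot
  p_hat <- rowSums(d, na.rm = TRUE) / (2 * n_called)
  maf <- pmin(p_hat, 1 - p_hat)
  list(
    missing_ok = miss_frac < thresholds$missing_max & n_called > 0,
    maf_ok = !is.na(maf) & maf > thresholds$maf_min,
    all_missing = n_called == 0
  )
}

#' Mask low-quality genotypes to missing
#'
#' The optional pre-structure stage: genotypes with quality below
#' `gq_min` are set missing (the matrix itself is not re-filtered).
#' A matrix without GQ is returned unchanged.
#'
#' @param gm A [genotype_matrix()].
#' @param gq_min Quality cutoff; genotypes with `GQ >= gq_min` are kept.
#' @return A `genotype_matrix` with failing genotypes set to `NA`.
#' @export
mask_low_gq <- function(gm, gq_min = 30) {
  if (is.null(gm$gq)) return(gm)
  d <- gm$dosage
  d[is.na(gm$gq) | gm$gq < gq_min] <- NA_integer_
  genotype_matrix(gm$sites, d, gq = gm$gq)
}

#' Apply the full site-filter stack
#'
#' Runs, in order: hard filters, biallelic, missingness, MAF, exact HWE
#' (pooled across the analysis samples by default, or within each
#' population when `hwe_by` gives population labels — a site then fails
#' if any population deviates). The report attributes each removed site
#' to the first rule it fails, so per-rule counts sum (with the kept
#' count) to the total.
#'
#' @param gm A [genotype_matrix()].
#' @param annotations Per-site annotation tibble aligned with `gm`
#'   (may be `NULL`: all sites pass the hard filters).
#' @param thresholds A [filter_thresholds()].
#' @param samples Optional analysis sample subset (columns kept in the
#'   output matrix).
#' @param hwe_by Optional named vector mapping sample id -> population
#'   for per-population HWE testing; default pooled.
#' @return A list with `gm` (filtered matrix), `report` (per-site tibble
#'   with `kept` and `rule`), and `counts` (per-rule summary tibble).
#' @export
apply_all_filters <- function(gm, annotations = NULL,
                              thresholds = filter_thresholds(),
                              samples = NULL, hwe_by = NULL) {
  n <- n_sites(gm)
  if (is.null(annotations)) {
    hard_ok <- rep(TRUE, n)
  } else {
    stopifnot(nrow(annotations) == n)
    hard_ok <- hard_filter(annotations, thresholds)
  }
  bi_ok <- biallelic_filter(gm)
  mm <- missingness_maf_filter(gm, samples, thresholds)

  rule <- rep(NA_character_, n)
  rule[!hard_ok] <- "hard_filter"
  set_if <- function(rule, mask, label) {
    rule[is.na(rule) & mask] <- label
    rule
  }
  rule <- set_if(rule, !bi_ok, "not_biallelic")
  rule <- set_if(rule, mm$all_missing, "all_missing")
  rule <- set_if(rule, !mm$missing_ok, "missingness")
  rule <- set_if(rule, !mm$maf_ok, "maf")

  # HWE only evaluated on sites still standing (exact test on the pooled
  # or per-population genotype counts)
  pending <- is.na(rule)
  if (any(pending)) {
    sub <- subset_gm(gm, sites = which(pending), samples = samples)
    if (is.null(hwe_by)) {
      p <- hwe_pvalues(sub)
      hwe_fail <- !is.na(p) & p < thresholds$hwe_alpha
    } else {
      pops <- split(names(hwe_by), unname(hwe_by))
      hwe_fail <- rep(FALSE, n_sites(sub))
      for (ids in pops) {
        ids <- intersect(ids, sample_ids(sub))
        if (length(ids) == 0) next
        p <- hwe_pvalues(sub, samples = ids)
        hwe_fail <- hwe_fail | (!is.na(p) & p < thresholds$hwe_alpha)
      }
    }
    rule[which(pending)[hwe_fail]] <- "hwe"
  }

  kept <- is.na(rule)
  report <- tibble(chrom = gm$sites$chrom, pos = gm$sites$pos,
                   kept = kept, rule = rule)
  counts <- report |>
    mutate(rule = ifelse(kept, "kept", .data$rule)) |>
    dplyr::count(.data$rule, name = "n_sites")
  if (!any(kept)) warn("all sites removed by filters")
  list(gm = subset_gm(gm, sites = which(kept), samples = samples),
       report = report, counts = counts)
}
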