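#' Run the full analysis pipeline
#'
#' Orchestrates: site filtering -> sliding-window diversity and FST per
#' contrast -> sweep scan per contrast -> coverage-based sex-chromosome
#' classification -> structure summaries (IBS distances, NJ tree, PCA),
#' then writes every artifact to `outdir` with a provenance header
#' (package version, config hash, seed). Stage failures abort with the
#' stage name.
#'
#' @param vcf Path to the input VCF.
#' @param meta Path to the sample-metadata TSV, or a metadata tibble.
#' @param outdir Output directory.
#' @param contrasts List of `c(reference, target)` population pairs.
#' @param chrom_lengths Named vector of chromosome lengths; default
#'   inferred as the last variant position per chromosome.
#' @param coverage Optional coverage TSV path or coverage tibble (enables
#'   the sex scan).
#' @param genes Optional BED/GFF3 path or gene tibble (enables gene
#'   overlap).
#' @param thresholds A [filter_thresholds()].
#' @param spec Optional [window_spec()]; default 5 kb / 2.5 kb on
#'   `chrom_lengths`.
#' @param sweep_q,sweep_epsilon Sweep-scan parameters.
#' @param sex_params A [sex_scan_params()].
#' @param pca_k Number of principal components.
#' @param gq_min Genotype-quality mask applied before the structure
#'   stage only (`NULL` disables).
#' @param seed Seed recorded in the provenance header (the pipeline
#'   itself is deterministic).
#' @return A list of class `pipeline_result`: `gm`, `filter_counts`,
#'   `window_stats`, `sweeps` (per contrast), `sex` (or `NULL`),
#'   `structure` (distances, tree, pca), `summary` (tibble), `files`.
#' @export
run_pipeline <- function(vcf, meta, outdir, contrasts,
                         chrom_lengths = NULL, coverage = NULL, genes = NULL,
                         thresholds = filter_thresholds(), spec = NULL,
                         sweep_q = 0.95, sweep_epsilon = 1e-5,
                         sex_params = sex_scan_params(), pca_k = 2,
                         gq_min = 30, seed = 1) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(meta)) meta <- read_sample_metadata(meta)
  pops_named <- unique(unlist(contrasts))
  if (!all(pops_named %in% meta$population)) {
    abort(paste0("contrast names population absent from metadata: ",
                 paste(setdiff(pops_named, meta$population), collapse = ", ")))
  }

  vv <- stage("read_vcf", read_vcf(vcf))
  filt <- stage("filter", apply_all_filters(
    vv$gm, vv$annotations, thresholds, samples = meta$sample))
  gm <- filt$gm

  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(gm$sites$pos, gm$sites$chrom, max)
    chrom_lengths <- setNames(as.integer(chrom_lengths), names(chrom_lengths))
  }
  if (is.null(spec)) spec <- window_spec(chrom_lengths)

  ws <- stage("windowstats",
              window_stats(gm, meta, spec, contrasts = contrasts))

  gene_tbl <- NULL
  if (!is.null(genes)) {
    gene_tbl <- if (is.character(genes)) read_intervals(genes) else genes
  }
  sweeps <- list()
  for (ct in contrasts) {
    key <- paste0(ct[1], "_vs_", ct[2])
    sweeps[[key]] <- stage(paste0("sweep:", key),
                           sweep_scan(ws, ct[1], ct[2], q = sweep_q,
                                      epsilon = sweep_epsilon,
                                      genes = gene_tbl))
  }

  sex <- NULL
  if (!is.null(coverage)) {
    cov <- if (is.character(coverage)) read_coverage(coverage) else coverage
    sex <- stage("sexscan", classify_chromosomes(cov, meta, sex_params))
  }

  gm_struct <- if (!is.null(gq_min)) mask_low_gq(gm, gq_min) else gm
  dmat <- stage("distance", ibs_distance(gm_struct))
  tree <- if (n_samples(gm) >= 3) stage("njtree", nj_tree(dmat)) else NULL
  pca <- stage("pca", pca_genotypes(gm_struct, k = pca_k))

  pi_cols <- grep("^pi_", names(ws), value = TRUE)
  summary <- bind_rows(
    tibble(metric = paste0("median_", pi_cols),
           value = vapply(pi_cols, function(cl) median_stat(ws[[cl]]),
                          numeric(1))),
    tibble(metric = paste0("median_fst_",
                           vapply(contrasts, paste, character(1),
                                  collapse = "_")),
           value = vapply(contrasts, function(ct) {
             median_stat(ws[[paste0("fst_", ct[1], "_", ct[2])]])
           }, numeric(1))),
    tibble(metric = paste0("n_candidate_windows_", names(sweeps)),
           value = vapply(sweeps, function(s) sum(s$windows$candidate),
                          numeric(1))),
    tibble(metric = paste0("n_swept_genes_", names(sweeps)),
           value = vapply(sweeps, function(s) length(s$genes), numeric(1)))
  )

  prov <- c(
    paste0("invasweep ", as.character(utils::packageVersion("invasweep"))),
    paste0("seed=", seed),
    paste0("config_hash=", config_hash(list(
      thresholds = unclass(thresholds), spec = unclass(spec),
      sweep_q = sweep_q, sweep_epsilon = sweep_epsilon,
      contrasts = contrasts, pca_k = pca_k, gq_min = gq_min)))
  )
  files <- c(filtered_vcf = file.path(outdir, "filtered.vcf"),
             filter_report = file.path(outdir, "filter_report.tsv"),
             window_stats = file.path(outdir, "window_stats.tsv"),
             summary = file.path(outdir, "summary.tsv"))
  write_vcf(gm, files[["filtered_vcf"]])
  write_tsv_commented(filt$counts, files[["filter_report"]], prov)
  write_window_stats(ws, files[["window_stats"]], prov)
  write_tsv_commented(summary, files[["summary"]], prov)
  for (key in names(sweeps)) {
    f <- file.path(outdir, paste0("sweep_regions_", key, ".tsv"))
    files[[paste0("sweep_", key)]] <- f
    regions_out <- tidy(sweeps[[key]])
    if (nrow(regions_out) > 0) {
      regions_out <- regions_out |>
        mutate(start = .data$start + 1L)  # 1-based inclusive on disk
    }
    write_tsv_commented(regions_out, f, prov)
  }
  if (!is.null(sex)) {
    files[["sex_calls"]] <- file.path(outdir, "sex_calls.tsv")
    write_tsv_commented(sex$calls, files[["sex_calls"]], prov)
    files[["sex_windows"]] <- file.path(outdir, "sex_windows.tsv")
    write_tsv_commented(sex$windows, files[["sex_windows"]], prov)
  }
  if (!is.null(tree)) {
    files[["tree"]] <- file.path(outdir, "nj_tree.nwk")
    to_newick(tree, files[["tree"]])
  }
  files[["pca"]] <- file.path(outdir, "pca.tsv")
  write_tsv_commented(tidy(pca), files[["pca"]], prov)

  structure(list(gm = gm, filter_counts = filt$counts, window_stats = ws,
                 sweeps = sweeps, sex = sex,
                 structure = list(dist = dmat, tree = tree, pca = pca),
                 summary = summary, files = files),
            class = "pipeline_result")
}

# stable short hash of the configuration (provenance only)
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 257)) %%
            .Machine$integer.max)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$summary, n = 30)
  invisible(x)
}
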