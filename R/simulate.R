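#' Simulation configuration
#'
#' Describes a simulated resequencing study: chromosomes with a sex type,
#' populations of diploids differentiated under the Balding-Nichols
#' model, optional admixed individuals, optional selective sweeps in a
#' target population, and the coverage model. Defaults follow the study
#' design the package targets: 17x mean depth, 1-kb coverage windows,
#' ancestral frequencies Uniform(0.05, 0.95), and pure Poisson per-window
#' depth (set `depth_noise_sd > 0` to add per-sample lognormal
#' library-size factors).
#'
#' @param seed Integer RNG seed; every emitted artifact is deterministic
#'   given the seed.
#' @param chromosomes Tibble (or data frame) with columns `name`,
#'   `length` (bp), `type` in `{"autosome", "X", "Y"}`.
#' @param populations Tibble with columns `label`, `n` (diploids), `f`
#'   (Balding-Nichols differentiation in `[0, 1)`).
#' @param site_density Expected variant sites per bp (autosomes carry the
#'   genotypes; X/Y chromosomes contribute coverage only).
#' @param freq_range Range of the uniform ancestral-frequency sampler.
#' @param sweeps Optional tibble `chrom`, `start`, `end`, `target`,
#'   `alpha`: in the target population, site frequencies inside the
#'   interval are pushed toward the nearer fixation with intensity
#'   `alpha`.
#' @param admixed Optional tibble `sample`, `sex`, plus one `q_<label>`
#'   ancestry-proportion column per population (rows summing to 1).
#' @param mean_depth Mean read depth per sample (diploid dosage).
#' @param depth_noise_sd Lognormal sdlog of the per-sample depth factor
#'   (0 = none).
#' @param y_female_background Fraction of nominal depth that females
#'   receive on Y (mismapping background), default 0.02.
#' @param coverage_window Coverage window width in bp (default 1000).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       chromosomes = tibble(name = "chr1", length = 1e6,
                                            type = "autosome"),
                       populations = tibble(label = c("POP1", "POP2"),
                                            n = c(10, 10), f = c(0.05, 0.05)),
                       site_density = 0.01,
                       freq_range = c(0.05, 0.95),
                       sweeps = NULL,
                       admixed = NULL,
                       mean_depth = 17,
                       depth_noise_sd = 0,
                       y_female_background = 0.02,
                       coverage_window = 1000) {
  chromosomes <- as_tibble(chromosomes)
  populations <- as_tibble(populations)
  stopifnot(all(chromosomes$type %in% c("autosome", "X", "Y")),
            all(populations$f >= 0 & populations$f < 1),
            site_density > 0, mean_depth > 0, depth_noise_sd >= 0,
            freq_range[1] > 0, freq_range[2] < 1,
            freq_range[1] < freq_range[2])
  if (!is.null(sweeps)) {
    sweeps <- as_tibble(sweeps)
    stopifnot(all(sweeps$alpha >= 0 & sweeps$alpha <= 1),
              all(sweeps$target %in% populations$label))
  }
  if (!is.null(admixed)) {
    admixed <- as_tibble(admixed)
    qc <- paste0("q_", populations$label)
    stopifnot(all(qc %in% names(admixed)))
    qs <- rowSums(as.matrix(admixed[qc]))
    stopifnot(all(abs(qs - 1) < 1e-8))
  }
  structure(list(seed = as.integer(seed), chromosomes = chromosomes,
                 populations = populations, site_density = site_density,
                 freq_range = freq_range, sweeps = sweeps, admixed = admixed,
                 mean_depth = mean_depth, depth_noise_sd = depth_noise_sd,
                 y_female_background = y_female_background,
                 coverage_window = as.integer(coverage_window)),
            class = "sim_config")
}

#' Balding-Nichols population allele frequency
#'
#' Draws a population frequency around the ancestral frequency `p_anc`
#' with differentiation `f`: `Beta(p (1-f)/f, (1-p)(1-f)/f)`, whose mean
#' is `p_anc` and variance `p_anc (1 - p_anc) f` — so `f` equals the
#' expected FST between populations drawn this way. `f = 0` returns
#' `p_anc` unchanged.
#'
#' @param p_anc Ancestral frequencies in (0, 1) (vectorised).
#' @param f Differentiation parameter in `[0, 1)`.
#' @return Population frequencies, same length as `p_anc`.
#' @export
bn_population_freq <- function(p_anc, f) {
  stopifnot(all(p_anc > 0 & p_anc < 1), f >= 0, f < 1)
  if (f == 0) return(p_anc)
  rbeta(length(p_anc), p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
}

#' Push an allele frequency toward fixation (sweep injection)
#'
#' `p' = (1 - alpha) p + alpha * 1[p >= 0.5]`: frequencies move toward
#' the nearer fixation point with intensity `alpha`, reducing expected
#' heterozygosity `p'(1 - p') <= p(1 - p)` and raising differentiation
#' against an unswept population.
#'
#' @param p Frequencies (vectorised).
#' @param alpha Sweep intensity in `[0, 1]`.
#' @return Swept frequencies.
#' @export
inject_sweep <- function(p, alpha) {
  stopifnot(alpha >= 0, alpha <= 1)
  (1 - alpha) * p + alpha * (p >= 0.5)
}

#' Site density matching a target per-bp diversity
#'
#' Under the generator, the expected per-bp diversity of one population
#' is `density * E[2 p (1 - p)] * (1 - f)` with `p` uniform on
#' `freq_range`. Inverts that relationship so simulated genomes hit a
#' target genome-wide diversity (e.g. a published estimate).
#'
#' @param target_pi Target per-bp nucleotide diversity.
#' @param f Population differentiation parameter.
#' @param freq_range Ancestral-frequency sampler range.
#' @return Sites per bp.
#' @export
calibrate_site_density <- function(target_pi, f = 0, freq_range = c(0.05, 0.95)) {
  a <- freq_range[1]; b <- freq_range[2]
  # E[p] and E[p^2] for Uniform(a, b)
  ep <- (a + b) / 2
  ep2 <- (b^3 - a^3) / (3 * (b - a))
  e_het <- 2 * (ep - ep2)
  target_pi / (e_het * (1 - f))
}

#' Simulate a genotype panel with known truth
#'
#' Variant positions fall uniformly at `site_density` on the autosomes;
#' each population's site frequencies are Balding-Nichols draws around a
#' shared ancestral frequency, optionally pushed toward fixation inside
#' sweep intervals of the target population; dosages are Binomial(2, p).
#' Admixed individuals draw each of their two gene copies from ancestry
#' `k` with probability `q_k`, at that population's frequency. Sex labels
#' alternate F/M within each population. All randomness flows from a
#' single RNG stream seeded by `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_genotypes`: `gm` (a
#'   [genotype_matrix()]), `meta` (sample metadata tibble), `truth`
#'   (list: `site_freq` tibble of per-site per-population frequencies,
#'   `sweeps`, `ancestry`, `chromosomes`).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  auto <- cfg$chromosomes |> filter(.data$type == "autosome")
  if (nrow(auto) == 0) abort("need at least one autosome for genotypes")

  pops <- cfg$populations
  meta <- pops |>
    purrr::pmap(function(label, n, f) {
      tibble(sample = sprintf("%s_%02d", label, seq_len(n)),
             population = label,
             sex = rep(c("F", "M"), length.out = n))
    }) |>
    bind_rows()

  sites_l <- list(); freq_l <- list(); dos_l <- list()
  for (ci in seq_len(nrow(auto))) {
    ch <- auto$name[ci]; len <- auto$length[ci]
    n_sites <- rpois(1, cfg$site_density * len)
    pos <- sort(sample.int(len, min(n_sites, len)))
    ns <- length(pos)
    p_anc <- runif(ns, cfg$freq_range[1], cfg$freq_range[2])
    pf <- matrix(NA_real_, ns, nrow(pops),
                 dimnames = list(NULL, pops$label))
    for (pi in seq_len(nrow(pops))) {
      pf[, pi] <- bn_population_freq(p_anc, pops$f[pi])
    }
    if (!is.null(cfg$sweeps)) {
      sw <- cfg$sweeps |> filter(.data$chrom == ch)
      for (si in seq_len(nrow(sw))) {
        in_sw <- (pos - 1L) >= sw$start[si] & (pos - 1L) < sw$end[si]
        tgt <- sw$target[si]
        pf[in_sw, tgt] <- inject_sweep(pf[in_sw, tgt], sw$alpha[si])
      }
    }
    dos <- matrix(NA_integer_, ns, nrow(meta),
                  dimnames = list(NULL, meta$sample))
    for (pi in seq_len(nrow(pops))) {
      ids <- meta$sample[meta$population == pops$label[pi]]
      dos[, ids] <- rbinom(ns * length(ids), 2, pf[, pi])
    }
    sites_l[[ci]] <- tibble(chrom = ch, pos = pos,
                            ref = "A", alt = "T", p_anc = p_anc)
    freq_l[[ci]] <- as_tibble(pf) |> mutate(chrom = ch, pos = pos)
    dos_l[[ci]] <- dos
  }
  sites <- bind_rows(sites_l)
  dosage <- do.call(rbind, dos_l)

  # admixed individuals: each gene copy from ancestry k w.p. q_k
  ancestry <- NULL
  if (!is.null(cfg$admixed)) {
    qc <- paste0("q_", pops$label)
    freqs <- as.matrix(bind_rows(freq_l)[pops$label])
    ad <- matrix(NA_integer_, nrow(sites), nrow(cfg$admixed),
                 dimnames = list(NULL, cfg$admixed$sample))
    for (ai in seq_len(nrow(cfg$admixed))) {
      q <- as.numeric(cfg$admixed[ai, qc])
      copy <- function() {
        k <- sample.int(length(q), nrow(freqs), replace = TRUE, prob = q)
        rbinom(nrow(freqs), 1, freqs[cbind(seq_len(nrow(freqs)), k)])
      }
      ad[, ai] <- copy() + copy()
    }
    dosage <- cbind(dosage, ad)
    meta <- bind_rows(meta, tibble(sample = cfg$admixed$sample,
                                   population = "ADMIXED",
                                   sex = cfg$admixed$sex))
    ancestry <- cfg$admixed
  }

  gm <- genotype_matrix(sites |> select("chrom", "pos", "ref", "alt"), dosage)
  truth <- list(
    site_freq = bind_rows(freq_l) |>
      select("chrom", "pos", all_of(pops$label)),
    sweeps = cfg$sweeps, ancestry = ancestry,
    chromosomes = cfg$chromosomes
  )
  structure(list(gm = gm, meta = meta, truth = truth, config = cfg),
            class = "sim_genotypes")
}

#' Simulate a per-window coverage track with sex-linked dosage
#'
#' Per 1-kb window and sample, depth is Poisson with mean
#' `mean_depth * c_s * G`: `c_s` a per-sample lognormal factor (identity
#' when `depth_noise_sd = 0`) and `G` the dosage of the window's
#' chromosome — autosome 1 for both sexes; X female 1, male 0.5; Y female
#' `y_female_background`, male 0.5.
#'
#' @param cfg A [sim_config()].
#' @param meta Optional metadata tibble (`sample`, `sex`); default 5
#'   females + 5 males.
#' @return A list of class `sim_coverage`: `coverage` (tibble `chrom`,
#'   `start`, `end`, one depth column per sample), `meta`, `truth`
#'   (chromosome types and per-sample factors).
#' @export
simulate_coverage <- function(cfg, meta = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)  # distinct stream from the genotype draw
  if (is.null(meta)) {
    meta <- tibble(sample = sprintf("S%02d", 1:10),
                   population = "SIM",
                   sex = rep(c("F", "M"), each = 5))
  }
  cs <- if (cfg$depth_noise_sd > 0) {
    rlnorm(nrow(meta), meanlog = -cfg$depth_noise_sd^2 / 2,
           sdlog = cfg$depth_noise_sd)
  } else rep(1, nrow(meta))
  dosage_of <- function(type, sex) {
    dplyr::case_when(
      type == "autosome" ~ 1,
      type == "X" & sex == "F" ~ 1,
      type == "X" & sex == "M" ~ 0.5,
      type == "Y" & sex == "F" ~ cfg$y_female_background,
      type == "Y" & sex == "M" ~ 0.5,
      .default = 1
    )
  }
  rows <- list()
  for (ci in seq_len(nrow(cfg$chromosomes))) {
    ch <- cfg$chromosomes[ci, ]
    starts <- seq(0L, ch$length - 1L, by = cfg$coverage_window)
    ends <- pmin(starts + cfg$coverage_window, ch$length)
    nw <- length(starts)
    depth <- matrix(0, nw, nrow(meta), dimnames = list(NULL, meta$sample))
    for (si in seq_len(nrow(meta))) {
      g <- dosage_of(ch$type, meta$sex[si])
      depth[, si] <- rpois(nw, cfg$mean_depth * cs[si] * g)
    }
    rows[[ci]] <- bind_cols(tibble(chrom = ch$name, start = starts, end = ends),
                            as_tibble(depth))
  }
  coverage <- validate_coverage(bind_rows(rows))
  truth <- list(chromosomes = cfg$chromosomes,
                sample_factor = setNames(cs, meta$sample))
  structure(list(coverage = coverage, meta = meta, truth = truth,
                 config = cfg),
            class = "sim_coverage")
}

#' Simulate a non-overlapping gene annotation with categories
#'
#' Places `n_genes` non-overlapping intervals uniformly on the simulated
#' chromosomes and assigns each gene one of `n_categories` functional
#' categories at random (the substrate for overlap and enrichment
#' testing).
#'
#' @param cfg A [sim_config()].
#' @param n_genes Number of genes.
#' @param n_categories Number of functional categories.
#' @param gene_length Fixed gene length in bp.
#' @return A list: `genes` (tibble `chrom`, `start`, `end`, `gene_id`),
#'   `categories` (tibble `gene_id`, `category`).
#' @export
simulate_gene_annotation <- function(cfg, n_genes = 200, n_categories = 10,
                                     gene_length = 2000) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  chroms <- cfg$chromosomes
  slots_per <- pmax((chroms$length %/% (2L * gene_length)) - 1L, 0L)
  if (sum(slots_per) < n_genes) abort("genes do not fit in the genome")
  alloc <- table(sample(rep(seq_len(nrow(chroms)), slots_per))[seq_len(n_genes)])
  out <- list()
  for (ci in names(alloc)) {
    i <- as.integer(ci)
    k <- as.integer(alloc[[ci]])
    slots <- sort(sample.int(slots_per[i], k))
    start <- (slots - 1L) * 2L * gene_length +
      sample.int(gene_length, k, replace = TRUE)
    out[[ci]] <- tibble(chrom = chroms$name[i], start = start,
                        end = start + gene_length)
  }
  genes <- bind_rows(out) |>
    arrange(.data$chrom, .data$start) |>
    mutate(gene_id = sprintf("gene%04d", row_number()))
  categories <- tibble(
    gene_id = genes$gene_id,
    category = sprintf("CAT%02d", sample.int(n_categories, nrow(genes),
                                             replace = TRUE))
  )
  list(genes = genes, categories = categories)
}

#' Write simulator outputs to files
#'
#' Emits the VCF, metadata TSV, coverage TSV, gene BED and truth JSON for
#' a simulated study — the on-disk fixture layout the pipeline consumes.
#'
#' @param sim A `sim_genotypes` result.
#' @param outdir Output directory (created if needed).
#' @param coverage Optional `sim_coverage` result.
#' @param annotation Optional [simulate_gene_annotation()] result.
#' @return Named character vector of the files written.
#' @export
write_sim <- function(sim, outdir, coverage = NULL, annotation = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(vcf = file.path(outdir, "genotypes.vcf"),
             meta = file.path(outdir, "samples.tsv"))
  write_vcf(sim$gm, paths[["vcf"]])
  readr::write_tsv(sim$meta, paths[["meta"]])
  if (!is.null(coverage)) {
    paths[["coverage"]] <- file.path(outdir, "coverage.tsv")
    readr::write_tsv(as_tibble(coverage$coverage), paths[["coverage"]])
  }
  if (!is.null(annotation)) {
    paths[["genes"]] <- file.path(outdir, "genes.bed")
    readr::write_tsv(annotation$genes |>
                       select("chrom", "start", "end", "gene_id"),
                     paths[["genes"]], col_names = FALSE)
    paths[["categories"]] <- file.path(outdir, "categories.tsv")
    readr::write_tsv(annotation$categories, paths[["categories"]])
  }
  paths
}
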