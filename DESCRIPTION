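Package: invasweep
Title: Selective-Sweep, Sex-Chromosome and Population-Structure Scans for
    Resequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for the population-genomic analysis of
    invasive-species resequencing panels. Reads multi-sample SNP VCFs into a
    dosage matrix, applies GATK-style hard filters plus biallelic, missingness,
    minor-allele-frequency and exact Hardy-Weinberg filters, computes sliding
    window nucleotide diversity and Weir-Cockerham fixation index (weighted,
    ratio-of-sums), and calls candidate selective sweeps as the intersection of
    upper-quantile outliers of FST and of the between-population diversity
    ratio, with gene overlap and hypergeometric enrichment. Identifies sex
    chromosomes from female:male read-coverage ratios in 1-kb windows, and
    summarises population structure via identity-by-state distances,
    neighbor-joining trees and Patterson-normalised principal components. A
    Balding-Nichols genotype and coverage simulator with known truth supports
    parameter-recovery validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    rtracklayer,
    S4Vectors,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
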