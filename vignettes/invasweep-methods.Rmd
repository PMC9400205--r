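---
title: "Models and methods behind invasweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind invasweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invasweep)
library(tibble)
```

`invasweep` implements the population-genomic core of a resequencing
study of an invasive insect: which genomic windows differentiate an
introduced population from its source, which of those carry the joint
signature of a selective sweep, which chromosomes are sex-linked, and
how the samples cluster. This vignette explains the models, the
defaults, and the choices made where a published description left the
design open.

## Site filtering

Variant sites pass five stages, in order: GATK-style hard filters on
the INFO annotations (`QD < 2.0 || MQ < 40.0 || FS > 60.0 || SOR > 3.0
|| MQRankSum < -12.5 || ReadPosRankSum < -8.0`), biallelic-only,
genotype missing rate < 10%, minor allele frequency > 0.05, and an
exact Hardy–Weinberg test at α = 0.001. Three details matter:

- **Inequalities are strict exactly as written.** A site at
  missingness = 10%, MAF = 0.05 or MQ = 40.0 is on the *failing* side
  of the missingness/MAF rules and the *passing* side of the MQ rule,
  respectively; the test suite pins these boundaries.
- **Missing annotations never fail a site.** Rank-sum annotations are
  undefined for sites without heterozygous carriers; failing such sites
  would silently bias toward high-frequency variants. This is the usual
  variant-caller convention.
- **HWE is tested pooled across the analysis samples by default.** The
  filter feeds one genome-wide SNP set used by all downstream analyses,
  so the default mirrors filtering one global VCF; `hwe_by` switches to
  per-population testing (a site then fails if any population
  deviates), which is the statistically cleaner choice when population
  structure is strong — pooled testing removes some strongly
  differentiated sites via the Wahlund effect.

The exact HWE p-value is Levene's conditional test: given `n` diploids
and the minor-allele count, the heterozygote count `h` has
`P(h) ∝ n! 2^h / (n_AA! h! n_aa!)`, and the two-sided p-value sums all
outcomes no more probable than the observed one (no mid-p). The
implementation evaluates the distribution by a log-space ratio
recurrence, so it is stable for thousands of samples; the tests check
it against a direct factorial-formula enumeration for every genotype
configuration up to n = 20.

A separate, optional stage masks genotypes with quality below 30 to
missing. It is applied before the structure analyses (distances, PCA)
only, where per-genotype quality matters most, and not before the
windowed statistics, matching how the upstream study used it.

## Windows

Statistics are computed on sliding windows of 5 kb advanced by 2.5 kb
(both configurable). A chromosome yields every full window plus at most
one truncated terminal window; a chromosome shorter than one window
yields a single truncated window. This convention reproduces the usual
windowed-statistics tables while avoiding a tail of tiny,
noise-dominated fragments at chromosome ends. Window coordinates are
0-based half-open internally and 1-based inclusive on disk (the
`BIN_START`/`BIN_END` dialect of the common tools).

## Diversity and differentiation

Per-site diversity is the unbiased pairwise estimator
`2j(n−j)/(n(n−1))` for `j` alternate alleles among `n` called alleles;
windowed diversity divides the site sum by the window *span*, counting
non-variant positions as zero (the convention of the standard windowed-π
tools; a per-variant-site denominator is available as an option).
Windows with no usable variant are flagged and excluded from medians
and quantiles rather than being reported as π = 0 — an absence of
calls is not evidence of zero diversity.

Differentiation uses the Weir–Cockerham (1984) variance components for
two populations, with per-site sample sizes (missing genotypes shrink
`n_i` site by site). Windows combine sites as a ratio of sums,
`Σa / Σ(a+b+c)` — the "weighted" estimator — which is far less noisy
than averaging per-site ratios. Negative window estimates are retained:
clamping at zero would shift the upper-quantile threshold of the sweep
scan. Genome-wide summaries are window-level medians, and distributions
between contrasts are compared with the two-sided Mann–Whitney test
(normal approximation with tie correction).

## The sweep scan

For a contrast (reference population, target population) the scan
computes per window the diversity ratio
`ρ = (π_ref + ε)/(π_target + ε)`, oriented so that diversity *loss in
the target* gives large ρ. The pseudocount ε = 1e−5 keeps
zero-diversity windows finite; it sits well below any plausible per-bp
diversity, so it cannot reorder non-degenerate windows. Outliers of
each statistic are defined by an order-statistic threshold: the
`⌈qW⌉`-th smallest of the `W` usable values, flagging values strictly
greater. This rule is tie-safe (a constant vector flags nothing) and
flags exactly `(1−q)·W` windows for distinct values when `W` is a
multiple of `1/(1−q)`. Candidate sweep windows are the *intersection*
of the two outlier sets; windows unusable for either statistic are
excluded entirely. Overlapping or book-ended candidates merge into
regions (no published merge rule existed; book-ended merging is the
natural choice for a half-open tiling), regions take peak statistics
over member windows, and genes overlap by at least one base pair under
half-open arithmetic. Enrichment of the swept gene set is the
upper-tail hypergeometric test per category with Benjamini–Hochberg
correction across categories.

## Sex-chromosome classification

With equal sequencing effort, autosomes show equal female and male
coverage, the X twice the coverage in females (males are hemizygous),
and the Y female coverage near zero. The classifier computes per-1-kb
window the mean depth per sex group and
`log2((F̄ + δ)/(M̄ + δ))` with δ = 0.1 depth units — large enough to
keep zero-female Y windows finite, small enough (≪ 17× depth) to leave
autosome and X ratios untouched. Windows with male mean depth below
1× are unusable (their ratio reflects the pseudocount, not dosage).
The chromosome call is made on the *median* log2 ratio over usable
windows — robust to mismapped windows — with bands: autosome
`|m| ≤ 0.35`, X `|m − 1| ≤ 0.35`, Y `m ≤ −1`, otherwise undetermined,
and chromosomes with fewer than 10 usable windows undetermined. The
±0.35 half-width splits the distance between the expected modes at 0
and 1 symmetrically while tolerating Poisson noise at ≥ 10× depth; the
Y rule is the literal published cut. All bands are parameters of
`sex_scan_params()`.

## Structure summaries

Pairwise distance is `1 − IBS`: over sites where both samples are
called, one minus the fraction of alleles identical by state. Only the
matrix's role (input to neighbor-joining) is fixed by the upstream
design, so the simplest standard convention was adopted. The NJ tree
(Saitou–Nei, exact on additive matrices) comes from `ape`; negative
branch lengths, which NJ can produce on noisy input, are clamped to
zero for output with the raw values retained. Newick serialisation
quotes labels containing whitespace or metacharacters and round-trips
exactly.

PCA follows the Patterson/smartpca convention: missing dosages
mean-imputed, each site centred by `2p̂` and scaled by
`sqrt(2p̂(1−p̂))`, sites fixed in the sample dropped, and the sample
covariance eigendecomposed. Coordinates are eigenvectors scaled by the
square root of their eigenvalues; eigenvector sign is arbitrary and
tests compare up to sign.

## The simulator

`simulate_genotypes()` draws, per site, an ancestral frequency from
Uniform(0.05, 0.95) and per population a Balding–Nichols frequency
`Beta(p(1−F)/F, (1−p)(1−F)/F)`, whose variance `p(1−p)F` makes `F` the
expected F_ST between populations — so the published median F_ST values
can be plugged in directly as simulation parameters. Genotypes are
Binomial(2, p) per diploid; admixed individuals draw each gene copy
from ancestry `k` with probability `q_k`. Sweeps push target-population
frequencies toward the nearer fixation point,
`p' = (1−α)p + α·1[p ≥ 0.5]`, which provably never increases expected
heterozygosity and raises differentiation against an unswept
reference. Sites are unlinked: no recombination or linkage is modelled.
That is adequate here because every implemented statistic is
site-decomposable, but it means the simulator does not reproduce the
autocorrelation of window statistics along real chromosomes, the decay
flanks of real sweeps, or background selection — recovery tests
validate estimator calibration, not the realism of genomic
architecture. Singleton-free ascertainment, sequencing error and
genotype-caller artefacts are likewise not modelled.

`simulate_coverage()` draws per-window depth as
`Poisson(d · c_s · G)` with mean depth d = 17× (the study-scale
default), an optional per-sample lognormal factor `c_s`
(`depth_noise_sd`, default 0, i.e. pure Poisson — the cleanest
realisation of equal sequencing effort; raise it to model library-size
variation), and sex dosage `G`: autosome 1, X female 1 / male 0.5,
Y female 0.02 (mismapping background) / male 0.5.
`calibrate_site_density()` inverts the expected-diversity formula
`E[π/bp] = density · E[2p(1−p)] · (1−F)` so a simulated genome hits a
target genome-wide diversity such as a published estimate.

Each generator call seeds R's RNG from `config$seed` (coverage and
annotation use fixed small offsets so the three artifact families are
independently reproducible); identical configurations produce
byte-identical files.

## Problem sizes and numerical choices

The validation suite runs at desk scale, chosen so the whole test run
takes well under a minute of simulation time per experiment: F_ST
recovery uses 10+10 diploids and ~2.1×10⁵ sites on a 5-Mb genome
(recovering F within ±0.01); diversity recovery a 2-Mb genome
calibrated to π = 3×10⁻³ (within 10%); sweep recovery a 200-kb α = 0.9
sweep on 5 Mb (≥ 80% of fully-contained truth windows flagged, ≤ 1%
elsewhere); sex classification twenty seeded replicates of 1-Mb
chromosomes plus ratio checks on 10-Mb chromosomes. Degenerate inputs
are contracts, not crashes: empty chromosomes yield empty window sets,
windows without usable sites are excluded (never zero-filled), the
quantile rule refuses fewer than `1/(1−q)` usable windows, a sample
pair with no shared called site names itself in the error, and
monomorphic sites give HWE p = 1.

## Known limitations

Two-population F_ST only (no r > 2 estimator); no haplotype or
LD-based sweep statistics (XP-EHH and relatives), which are more
powerful for recent sweeps than the F_ST × π-ratio intersection; no
ancestry-likelihood model (ADMIXTURE-style) behind the admixture
summaries; coverage-based sex linkage only (no heterozygosity-based
inference); and the quantile intersection is an outlier rule, not a
model with controlled false-discovery — its yield depends on the
quantile `q` and on how much of the genome truly swept.
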