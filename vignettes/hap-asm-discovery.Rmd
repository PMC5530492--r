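---
title: "Discovering haplotype-dependent allele-specific methylation from small WGBS cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering haplotype-dependent allele-specific methylation from small WGBS cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapasm)
```

## The problem

Inter-individual differences in DNA methylation can be larger than
differences between cell types. At some loci the cause is genetic: the local
haplotype determines whether an allele becomes methylated
(haplotype-dependent allele-specific methylation, hap-ASM). In a region
under hap-ASM every cell carries one of two epialleles — essentially fully
methylated or essentially unmethylated — and an individual therefore has one
of three *epigenotypes*: both alleles methylated, both unmethylated, or one
of each. Bulk whole-genome bisulfite sequencing (WGBS) of such a region
shows methylation levels near 1, near 0, or near 0.5, respectively.

`hapasm` implements a complete pipeline for discovering such regions from a
small cohort of WGBS methylomes (the design case is five donors of the same
sex and cell type), attributing them to genotype, and characterising their
genomic context — together with a read-level cohort simulator so the whole
pipeline can be exercised and validated without access to restricted human
data.

## DMR discovery on synthetic extreme methylomes

With a handful of unlabelled samples there are no case/control groups, so a
two-group region caller does not apply. Instead, two *synthetic extreme
methylomes* are formed: at every aligned CpG `c` one takes the highest
methylation level across samples, `max(c)`, and the other the lowest,
`min(c)`. The per-CpG statistic is simply

    t(c) = max(c) - min(c)

Candidate regions are maximal runs of consecutive CpGs with `t(c) > v`
(default `v = 0.5`), broken at chromosome boundaries and wherever
consecutive CpGs are more than `max_gap` apart (default 300 bp, a common
within-region gap bound for WGBS region callers; the run-segmentation rule
itself does not bound gaps, so the bound is exposed as a parameter).

Because region borders are called imprecisely, each region's methylation
level per sample is summarised by the *core methylation*: an average of the
member-CpG levels weighted by the cross-sample standard deviation σ(c), so
that the CpGs where samples disagree most — the heart of the region — carry
the most weight:

    mu_i(d) = sum_c sigma(c) m_i(c) / sum_c sigma(c)

We normalise by Σσ(c) so that `mu` is a convex combination of levels and
stays in [0, 1]; this matters because the downstream beta-mixture stage
models `mu` on the unit interval, and because the ≥ 0.8 difference filter
below is only meaningful on the level scale. A variant normalised by the
CpG count `|C(d)|` instead (in which case `mu` is not bounded by 1 and
scales with the region's σ) is available as `core_norm = "count"` for
comparison.

A candidate becomes a DMR if it has at least `min_cpgs = 4` member CpGs and
the core methylations of the max- and min-envelope differ by at least
`min_core_diff = 0.8`. The 0.8 threshold has a biological reading: it
requires at least one sample to be close to homozygously methylated and
another close to homozygously unmethylated, i.e. a common, strong,
discrete difference — exactly the hap-ASM signature.

σ(c) is computed as the population standard deviation (divide by the number
of samples): it is defined for two samples, bounded by 0.5 for levels in
[0, 1], and only enters as a relative weight, so the choice of denominator
cancels in `mu`. A sample-variance form is available via `sd_type`.

An optional coverage-weighted kernel smoother (`smooth_methylome()`) is
provided for comparison experiments but is off by default: the envelope
statistic and the binomial null below both operate on raw levels, and
smoothing would correlate neighbouring sites under the null.

## Empirical significance: the pooled-rate binomial null

Under the null hypothesis that the samples share one methylome, the
per-CpG pooled rate is `p_c = (Σ_s m_s,c) / (Σ_s n_s,c)`. A null cohort is
simulated by keeping every sample's observed coverage and drawing
methylated counts `M_o,c ~ Binomial(n_s,c, p_c)` independently, so that any
cross-sample difference is finite-sampling noise. The caller is run on `R`
such replicate cohorts (default 1000). Every qualifying DMR found in a
replicate is by construction a false positive. With `k` the number of
replicates containing at least one qualifying call anywhere, every observed
DMR receives the family-level empirical p value `k/R`, reported as the
bound `< 1/R` when `k = 0`. At the default study scale (five samples,
~20,000 aligned CpGs, planted allele-specific differences) `k = 0` over
1000 replicates, so every DMR is reported at `p < 0.001`.

Two deliberate options: `method = "per_region"` counts, per observed DMR,
only replicates that produce a qualifying call overlapping that DMR's span
(the family-level "any region" count is the default because it reproduces
the `< 0.001 for each DMR` style of reporting exactly when `k = 0`); and
`estimator = "add_one"` gives the conservative `(k+1)/(R+1)` for users who
prefer a never-zero estimate. Replicate `r` is seeded with `seed + r`, so
any single replicate can be reproduced in isolation.

## How many regions are detectable? The Hardy–Weinberg model

The caller can only see a hap-ASM region if the cohort happens to contain
at least one individual homozygous for each epiallele. If epigenotypes
follow Hardy–Weinberg equilibrium with allele frequencies `p` and
`q = 1 - p`, inclusion–exclusion on the complementary event gives the
detection probability for `n` samples:

    P(p, q) = 1 - [ (1 - p^2)^n + (1 - q^2)^n - (2pq)^n ]

`detection_probability()` implements this closed form; `detection_rate()`
averages it over an allele-frequency spectrum (e.g. the dbSNP minor-allele
frequency spectrum above 0.05, supplied as a two-column TSV — no external
download is bundled); and `extrapolate_total()` converts an observed DMR
count into a population estimate by dividing by the rate. For five samples
and the published dbSNP-derived spectrum the rate is about 23%, which turns
157 observed regions into an estimated ~692 in the population.

## Epigenotype classification and SNP co-variation

Core methylations of hap-ASM regions concentrate near 0, 0.5 and 1, but
with noise from finite coverage and imprecise borders. Rather than fixed
thresholds, the pooled core methylations of *all* called DMRs across
samples are decomposed into a three-component beta mixture
("unmethylated", "half-methylated", "full-methylated"), fitted by EM:

* Initialisation is method-of-moments on a partition of [0, 1] at 1/3 and
  2/3, with 5 jitter restarts (deterministic given a seed); the best final
  log-likelihood wins.
* The M-step maximises each component's weighted beta log-likelihood
  numerically (BFGS on log-shape parameters), warm-started at the current
  parameters so the observed-data log-likelihood never decreases.
* Values are clamped to [1e-6, 1 - 1e-6]; convergence at Δlog-likelihood
  < 1e-8 or 500 iterations; components sorted by mean. Degenerate input
  (all values identical, too few values, non-finite values) errors loudly
  rather than returning NaNs.

Given the fitted mixture, the posterior that a methylation level `mu`
belongs to class `g` is `L(g, mu) = pi_g b_g(mu) / Σ_k pi_k b_k(mu)`, and a
SNP `s` is scored against a DMR `d` by the joint posterior over samples:

    score(s, d) = prod_i L(g_i(s), mu_i(d))

`scan_window()` scores every SNP within ±6 kb of the DMR centre (midpoint
of the member-CpG span; border-anchored available) and reports those
scoring above 0.9, the threshold calibrated for five samples. How the
threshold should scale with `n` is an open question; it is a plain
parameter.

**Orientation.** Which allele carries the methylated epiallele differs per
locus, so dosage 2 may mean "fully methylated" at one DMR and "fully
unmethylated" at another. The default policy scores both assignments
(class = dosage and class = 2 − dosage) and keeps the larger, reporting the
orientation used. This doubles sensitivity but also doubles the chance
that a random genotype vector matches by accident: for five
Hardy–Weinberg(0.5) genotypes containing both homozygote classes, a
uniformly random permutation of the genotypes reproduces the epigenotype
pattern with exact probability 0.063 under the both-orientations policy
versus 0.046 under a fixed orientation. Users who know the orientation
(e.g. from reads) can fix it via `orientation=`. Missing genotypes drop
out of the product and are flagged (`n_missing`), since a product over
fewer factors is not directly comparable across SNPs.

## Genomic context of the regions

`flank_profile()` compares each DMR's mean methylation with its flanks:
skip 3 CpGs on each side (border effects), average the next 10, and
classify by strict inequality into `lower_than_both`, `higher_than_both`,
`intermediate` (including ties), or `incomplete` when a flank has fewer
than 10 CpGs on the chromosome. Flank and region means are pooled
cross-sample means by default (`per_sample = TRUE` adds per-sample
columns). On hap-ASM landscapes most regions are methylation troughs in a
hypermethylated background, and the simulator reproduces this: its default
background methylation is Beta(7.2, 2.8), mean 0.72.

`enrichment_test()` asks whether DMRs over- or under-represent annotation
labels (chromatin states, gene features) by comparison with matched random
region sets: each set resamples the observed DMR length distribution with
replacement and places regions uniformly, rejecting placements inside the
repeat mask or covering fewer than 4 CpGs. `p_over` is the fraction of
random sets with a strictly higher per-label overlap count, `p_under` with
a strictly lower count; ties count to neither, so `p_over + p_under ≤ 1`.
The default is 10,000 sets at desk scale (the full-scale analysis used
1,000,000; `n_sets` is a parameter). The number of regions per set
defaults to the number of observed DMRs.

`state_difference_partition()` labels a DMR "different" between two donors
iff the sets of state labels overlapping it are disjoint, and
`rank_sum_compare()` (Mann–Whitney U; exact null for combined n ≤ 20
without ties, normal approximation with tie correction otherwise) compares
the absolute methylation differences of the two groups.

## The synthetic cohort generator

`simulate_genome()` / `simulate_cohort()` emulate the study conditions:

| parameter | default | rationale |
|---|---|---|
| `n_samples` | 5 | the design cohort size |
| `cpg_spacing` | 100 bp | exponential inter-CpG gaps, ~1 CpG per 100 bp |
| `coverage_lambda` | 30 | Poisson coverage, truncated ≥ 1, typical deep WGBS |
| `bg_alpha`, `bg_beta` | 7.2, 2.8 | background per-CpG mean ~ Beta, mean 0.72 |
| `dmr_width_cpgs` | 4–20 | planted region widths |
| `maf` | 0.5 | causal-SNP allele frequency (most detectable case) |
| `m_hi`, `m_lo` | 0.95, 0.05 | per-read methylation probability per epiallele |
| `epsilon` | 0 | mosaicism (probability a cell's allele flips state) |
| `dmr_internal_gap` | 250 bp | planted regions sit in CpG-dense sequence |
| `bg_snp_per_mb` | 50 | non-causal SNPs so window scans have negatives |

Simulation is at the read level: a causal SNP's genotypes are drawn from
Hardy–Weinberg equilibrium; each read at a planted CpG originates from one
of the two alleles with probability 1/2 and is methylated with probability
`m_hi` or `m_lo` according to that allele's epiallele state (flipped with
probability `epsilon`). Marginally the methylated count is exactly
binomial given the genotype — the same sampling family as the empirical
null, so the generator and the null machinery are mutually consistent.
Background CpGs are methylated per read at a site-specific Beta-distributed
mean shared across samples (a site property), which keeps background
cross-sample differences at binomial-noise scale.

The `dmr_internal_gap` constraint deserves a note: inter-CpG gaps are
exponential with mean 100 bp, so without it roughly 4 in 10 planted regions
of typical width would contain a gap above the caller's 300 bp `max_gap`
and be split by construction — a property of the gap model, not of the
method. Restricting planted regions to locally CpG-dense runs mirrors real
hap-ASM regions, which are CpG-dense and often CGI-adjacent.

What the generator does *not* model: sequencing error, incomplete
bisulfite conversion, read-length/fragment structure, correlated
methylation noise along reads, cell-type heterogeneity, or linkage
disequilibrium between SNPs (background SNP genotypes are independent).
Passing tests on synthetic cohorts therefore demonstrate correctness of
the algorithms under the stated generative model, not performance on real
methylomes with their additional noise structure.

Chromatin-state, gene-feature and repeat annotations are random tilings —
placeholders with the right geometry for exercising the enrichment
machinery, with no biological content. The repeat mask avoids planted
regions so that matched-region sampling remains comparable.

## Numerical and interface choices

* Coordinates are 1-based CpG positions (the C of the CpG, forward strand,
  strands merged) internally; BED I/O converts to 0-based half-open.
* `align_cohort()` keeps the intersection of sites covered ≥ `min_cov`
  (default 3) in every sample; missing sites are dropped, not imputed,
  because the envelope needs the max and min over all samples. The
  default suppresses single-read noise while keeping small fixtures valid.
* Ties in the envelope max/min are irrelevant (values are used, not which
  sample attains them).
* DMR start/end are reported as the span of member CpGs (no padding).
* Every stochastic operation takes an explicit seed; simulation functions
  save and restore the global RNG state, and derived seeds (`seed + r` per
  null replicate) make sub-computations independently reproducible.
* The empirical-null and caller path is vectorised (matrix binomial draws,
  `rle`-style run segmentation), so 1000 replicates on a 20,000-site
  five-sample cohort run in well under a minute.

## Problem sizes used in the shipped checks

The validation suite runs the full pipeline at desk scale, chosen so the
statistical claims are testable with comfortable margins: cohorts of
~20,000 aligned CpGs for the 1000-replicate null; 500 random mini-cohorts
(≤ 200 sites) for brute-force equivalence of the caller; 15 × 5 planted
DMRs for border-accurate recovery; 200 single-DMR cohorts for causal-SNP
scoring; 1001 matched random sets for enrichment self-calibration. The
mixture for scoring is fitted once on core methylations pooled from a
large run (~60 values), mirroring the pooled-fit design (one mixture per
study, not per region).

## Known limitations

* The caller's monotone run segmentation has no notion of nested or
  overlapping regions; a planted region interrupted by an aligned-site
  gap larger than `max_gap` is reported as split.
* The beta-mixture EM fits three components by design; cohorts whose DMR
  set lacks one class entirely (e.g. no heterozygotes) will fit a
  component to noise. At least 9 pooled values are required, and more are
  advisable; the pipeline skips scoring (with a note in the manifest)
  when fewer are available.
* The family-level empirical p is a bound, not a per-region tail
  probability; with `k > 0` the `per_region` method is the sharper choice.
* Enrichment p values inherit the granularity of `n_sets` and the tie
  structure of small overlap counts.

## A worked run

```{r, eval = FALSE}
cfg <- run_config(sim = sim_params(chrom_lengths = c(chrS1 = 2e6),
                                   n_planted_dmrs = 10),
                  null_replicates = 1000, seed = 1)
res <- run_pipeline(cfg)
res
res$dmrs[, c("dmr_id", "chrom", "start", "end", "n_cpgs",
             "envelope_diff", "p_label")]
head(res$scores)
table(res$flanks$class)
```
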