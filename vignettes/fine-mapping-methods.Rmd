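---
title: "Methods: simulation-validated fine-mapping of a candidate-gene region"
author: "candseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation-validated fine-mapping of a candidate-gene region}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

candseq re-implements, end to end, the computational chain of a targeted
resequencing fine-mapping study of a candidate-gene region in a
case-control cohort: variant discovery from sequencing pileups in a small
control panel, cohort-scale genotype QC and single-SNP association,
haplotype and LD analysis, an LD-aware gene-level test, an epistasis scan,
and a consistency statistic that asks whether a designated candidate SNP
behaves like the causal variant. Because the cohorts such studies draw on
are controlled-access, the package carries its own synthetic-data
generator whose output has known truth; every stage is validated against
that truth or against an independent oracle.

## The synthetic cohort generator

`make_haplotype_pool()` draws haplotypes through a Gaussian copula: a
latent standard-normal field with first-order autoregressive correlation
`ld_rho^|i-j|` between SNPs is thresholded per column at the quantile of a
target minor allele frequency drawn from `maf_range`. This choice is
deliberate: it reproduces the qualitative LD regimes of a candidate-gene
region (monotone decay, tunable strength) while keeping a closed-form
oracle — the implied two-SNP joint frequency is a bivariate-normal orthant
probability, so the expected r² of any pair can be computed by numerical
integration and compared with the simulated value. A coalescent simulator
would be more realistic (recombination hotspots, allele-frequency/LD
coupling, demography) but offers no such closed form; the tests rely on
the oracle heavily, so the copula wins. Columns that come out monomorphic
are dropped with a warning rather than resampled, keeping a fixed seed
byte-reproducible.

`simulate_cohort()` pairs pool haplotypes at random and assigns disease by
`logit P(case) = logit(prevalence) + log(OR) * g` at one causal SNP,
rejection-sampling until the case and control quotas are met exactly
(cap: 10^7 draws, then a loud `candseq_generation_failure`). Defaults are
the cohort scale of the motivating design (1738 cases, 1802 controls in
the analysis scripts), a baseline prevalence of 0.10 — a realistic
lifetime-scale figure for a common psychiatric disorder — and a
configurable odds ratio: published candidate-region hits in this family
of studies sit around OR 0.7-0.8 per allele, so the scripts use 1.3 on
the risk scale. Null-calibration runs use prevalence 0.5 purely for
rejection-sampling efficiency; under OR = 1 the phenotype is independent
of genotype, so the choice cannot affect any statistic's distribution.

`simulate_pileups()` gives each sample-site a Poisson(`mean_depth`) depth
and a Binomial alternative-read count with success probability
`error_rate`, 0.5 or `1 - error_rate` by genotype; errors are routed to
the site's alternative allele so that counts always sum to depth. This is
the simplest generative model the threshold caller can be validated
against exactly (a randomized-PIT/KS test in the suite confirms the
binomial law). It does not emulate strand bias, mapping error, indel
noise or GC-dependent coverage — so a green suite says the *caller logic*
is right, not that the thresholds are optimal on real reads.

`inject_missingness()` knocks out entries independently at per-SNP and
per-sample rates, which is exactly the failure mode the QC cascade
(below) is designed to catch; systematically clustered missingness
(plate effects) is not modelled.

## Variant calling from pileups

The caller is deliberately a faithful threshold rule, not a genotype
likelihood model: a site is emitted when depth lies within
`[min_coverage, max_coverage]` and the best non-reference allele carries
at least `het_alt_fraction` (default 0.35) of the reads; ties between
alternative alleles break alphabetically. `min_coverage` defaults to 20.
The maximum is the sample's "theoretical highest average coverage":
reads x read length / region length, computed per sample
(`max_coverage_threshold()`); in the analysis scripts a sample's read
total is its on-target bases inflated by the off-target fraction
(default on-target 27%), since the assayed sites — not the whole
chromosome — stand in for the sequenced region. Only the heterozygote
threshold is a published convention; the het/hom-alt boundary is not
stated anywhere, so the package uses the symmetric complement 0.65,
exposed as `hom_alt_fraction`. Indels and multi-allelic genotypes are out
of scope: sites are treated biallelically throughout, with non-best
alternative reads counted as non-supporting.

`merge_calls()` forms the cohort site list and allele frequency with the
convention that a sample with no call but callable depth is homozygous
reference, and a sample below `min_coverage` is missing — the
frequency denominator therefore varies per site.

## QC and single-SNP association

`qc_filter()` applies, in order and with recomputation after each step:
samples with more than 25% missing genotypes; SNPs with more than 10%
missing; SNPs with minor allele frequency below 1%; SNPs with
Hardy-Weinberg exact P below 1e-5. The HWE test is the exact conditional
test (sum of probabilities of heterozygote counts no more likely than
the observed one, evaluated in log space), computed in controls only by
default — equilibrium departures in controls indicate genotyping error,
while filtering on cases could discard a true signal; a flag switches to
the full cohort since practice varies. The association statistic is the
Pearson chi-square (1 df, no continuity correction) on the 2x2
allele-by-status table, with the cross-product odds ratio
(0.5 added to every cell only when some cell is zero) and 5e-8 as the
genome-wide flag. The suite verifies the algebraic identity between this
chi-square and the squared two-proportion z statistic, and calibrates the
type-I error on null cohorts.

The filter cascade is idempotent in practice but not by construction:
sample missingness is judged before SNP removal, so a pathological
configuration could shift a sample across the 25% line on a second pass.
The tests exercise the realistic regime (clear-cut exclusions plus low
background missingness), where a second pass is a no-op.

## Haplotypes and LD

`em_haplotype_freqs()` is a standard EM over haplotype-pair ambiguity
classes with a linkage-equilibrium start (product of allele
frequencies). The start matters only for degenerate inputs: a dataset of
lone double heterozygotes has a ridge of fixed points, and the product
start lands on the uniform one — this is documented behaviour, not an
accident. The log-likelihood trace is returned and asserted
non-decreasing in the tests. Individuals with missing genotypes in the
block are dropped before estimation (the alternative — summing over
missing patterns — buys little at block sizes of 2-8 SNPs).

`ld_stats()` reduces two-SNP estimation to the classic 3x3-table EM
(only the double heterozygote is ambiguous) and derives D, D' and r².
The D' confidence interval is a normalized likelihood profile over a
21-point grid on [0, 1] with 5% bounds on each side — the construction
that underlies confidence-interval ("Gabriel-style") block building in
the standard toolchain. `build_blocks()` then accepts a span when its
outermost pair is in strong LD (ci_low >= 0.70, ci_high >= 0.98) and at
least 95% of informative pairs inside are strong, taking candidate spans
longest-first without overlap. An optional pre-pass drops SNPs whose
maximum r² with the rest of the panel falls below a floor (off by
default), mirroring the ad-hoc practice of excluding weakly correlated
SNPs before re-blocking; the companion practice of excluding on
single-SNP P-values is noted but deliberately not automated, since it
mixes evidence with LD structure.

`haplotype_association()` tests each haplotype against all others on
EM-expected counts by status, pooling haplotypes below 1% frequency into
a "rare" class, and reduces exactly to the allelic test for single-SNP
blocks (asserted in the suite).

## Gene-level test

The gene statistic is the unweighted sum of the per-SNP 1-df chi-squares.
Its null is simulated: draw z ~ N(0, C) with C the genotype-dosage
correlation matrix of the gene's SNPs (the cohort itself is the LD
reference), sum the squared coordinates, and report the add-one empirical
P `(exceedances + 1) / (n_sims + 1)`. Pairwise-complete correlation
matrices from incomplete genotypes can be indefinite, so C is repaired by
flooring eigenvalues at 1e-8 and re-normalizing the diagonal before the
Cholesky factorization. SNP weighting is left unweighted by default — the
appropriate weights are genuinely unsettled — with an optional weight
argument. The defaults run one million simulations per gene; the test
suite and the analysis scripts use 10^4-10^5 so the whole chain stays in
interactive time, which costs empirical-P resolution below ~1e-4 but
nothing else. The suite pins the machinery to closed forms in the three
limits that have them: a single SNP (chi-square-1 survival), perfectly
correlated SNPs (collapse to one SNP), and an identity matrix
(chi-square-k survival).

## Epistasis scan

`pairwise_epistasis()` fits the full logistic interaction model
`status ~ g_a + g_b + g_a:g_b` on dosages — the documented default of the
standard toolchain — via the binomial GLM on genotype-aggregated counts
(at most nine cells; identical estimates and standard errors to the
per-individual fit, orders of magnitude faster). Separation and
non-convergence are flagged not-estimable rather than fatal. A fast
allele-count approximation (composite two-locus tables per status group,
difference of log odds ratios over its standard error) is available
behind a flag because which of the two modes produced any given published
scan is usually unknowable. Gene-group membership is an input table, not
hard-coded, and `gene_group_scan()` reports the planned test count and
Bonferroni threshold even in `plan_only` mode so a 416 x 1220 scan can be
sized before committing.

## Causal-variant consistency

`per_snp_logistic_z()` computes Wald Z-scores (slope / SE from the
univariate logistic fit). `consistency_fit()` regresses |Z| on the square
root of r² with a designated candidate: if the candidate (or a perfect
proxy of the causal variant) is causal, E|Z_j| tracks r_j |Z_c| and the
slope approaches the candidate's own |Z|; with no association the slope
approaches 0. Ordinary (unweighted) least squares is used — the source
analyses say only "linear fit" — and `compare_candidates()` ranks
candidates by slope.

Two open choices deserve their reasoning spelled out:

* **Absolute versus signed Z.** Absolute values match the published
  construction and need no allele alignment, but they put a
  folded-normal floor E|N(0,1)| = sqrt(2/pi) ≈ 0.80 under every
  unassociated point. A signed analysis (requiring alignment to the
  candidate's risk allele) is available behind a flag.
* **The candidate's own point.** An expected-value analysis of
  E|Z_j| = r_jc |Z_c| over an AR(1) window shows that with the
  candidate's own (r = 1, |Z|) point excluded, a moderate-LD proxy can
  fit a *steeper* line than the causal SNP itself — the far-LD arm of the
  window lies above the proxy's line — defeating the ranking the
  statistic exists for. Anchoring each candidate's fit with its own point
  restores the expected ordering (causal slope ~4.85 versus proxy ~3.5
  at |Z_c| = 5 and adjacent indicator correlation 0.9, window of 30
  SNPs). Both modes are exposed (`include_candidate`); the validation
  suite and the analysis scripts anchor.

The folded floor also touches the slope, not only the intercept: in the
anchored strong-LD design the measured downward bias of the slope as an
estimate of |Z_c| is about 3%, but it grows to 16-21% when many window
SNPs sit near r = 0 (their E|Z| ≈ 0.8 exceeds the line's prediction and
rotates it). The null direction is clean in any design: across >= 1000
replicate null cohorts the mean slope is statistically indistinguishable
from 0 (the acceptance script recomputes this with 1000 replicates of
1000 + 1000 samples over 60 SNPs, AR(1) rho 0.9).

## Problem sizes and numerical choices

The validation suite runs cohorts of 300-2500 samples and 4-2000 SNPs,
10^4-10^6 gene-test simulations, 150-250 replicate cohorts for the null
slope, and 8 replicates for the causal-slope recovery; the analysis
scripts use the full 1738 + 1802 cohort over a 150-SNP panel. EM
tolerances are 1e-8 (haplotypes) and 1e-10 (two-locus); GLMs run IRLS to
1e-8; separation is flagged at |beta| > 15. Empirical P-values are never
0 by construction. Percentages destined for summary tables round half
away from zero (`round_half_up()`), matching how published tables are
rounded rather than R's banker's rounding.

## What passing tests do and do not show

The generator's LD is stationary AR(1) with independent uniform mafs: no
hotspots, no maf-LD correlation, no population structure, no relatedness
(one control per family is the matching real-world convention), no
differential genotyping error between cases and controls. Calibration and
recovery results transfer to real cohorts only insofar as those features
do not dominate; the package's claim is that the *implementations* are
correct against known truth, not that the study design is robust to
confounding it never modelled.
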