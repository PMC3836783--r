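# candseq

Fine-mapping a disease-associated candidate-gene region usually ends in a
question the single-SNP scan cannot answer: is the best-associated common
variant itself causal, or merely a passenger in linkage disequilibrium
(LD) with the causal one? candseq implements, as tested R functions, the
complete downstream chain of a targeted resequencing fine-mapping study
of a case-control cohort — variant discovery in a small sequenced control
panel, cohort-scale QC and association, haplotype/LD analysis, gene-level
testing, epistasis scanning, and a causal-consistency statistic — plus a
synthetic-data generator that makes every stage testable without access
to controlled-access cohort genotypes. It is written for statistical
geneticists who want a desk-scale, fully inspectable re-implementation of
this analysis style with known-truth validation.

## What is implemented

* **Synthetic cohorts** — haplotypes from a Gaussian-copula AR(1) latent
  field (`make_haplotype_pool`), diploid case-control sampling under a
  logistic disease model with one causal SNP (`simulate_cohort`),
  Poisson/binomial sequencing pileups (`simulate_pileups`) and injected
  missingness (`inject_missingness`).
* **Threshold variant calling** — per-sample calls from pileup allele
  counts: depth within [20x, per-sample theoretical maximum
  = reads x read length / region length], heterozygote when ≥ 35% of
  reads carry the best alternative allele (`call_sample_variants`,
  `merge_calls`, `coverage_summary`).
* **QC + association** — exclusion cascade (samples > 25% missing,
  SNPs > 10% missing, maf < 1%, exact Hardy-Weinberg P < 1e-5 in
  controls), then the allelic test per SNP (`qc_filter`, `assoc_scan`):
  Pearson χ² (1 df) on the 2×2 allele-by-status table, odds ratio as the
  cross-product ratio, 5×10⁻⁸ flagged genome-wide significant.
* **Haplotypes and LD** — EM haplotype frequencies
  (`em_haplotype_freqs`), D/D′/r² with likelihood-profile D′ confidence
  intervals (`ld_stats`), confidence-interval haplotype blocks
  (`build_blocks`) and per-haplotype association
  (`haplotype_association`).
* **Gene-level test** — T = Σⱼ χ²ⱼ over a gene's SNPs with an empirical
  null drawn as z ~ N(0, C), C the local genotype LD matrix, and
  P = (#{T_sim ≥ T} + 1)/(n_sims + 1) (`gene_test`,
  `ld_correlation_matrix`, `bonferroni_gene_threshold`).
* **Epistasis** — logistic interaction model
  status ~ g_a + g_b + g_a·g_b with a Wald test on the product term,
  plus a fast allele-count approximation (`pairwise_epistasis`,
  `gene_group_scan`).
* **Causal consistency** — per-SNP Wald Z = β̂/SE(β̂) from univariate
  logistic fits (`per_snp_logistic_z`), then the ordinary-least-squares
  fit of |Z| on √r² with a candidate SNP (`consistency_fit`,
  `compare_candidates`): a causal candidate's slope approaches its own
  |Z|; under the null the slope approaches 0.

The numbered scripts under `analysis/` run the chain as a narrative
(simulate → call → QC/associate → blocks → gene test → epistasis →
consistency), writing tables under `results/`. The methods vignette
(`vignettes/fine-mapping-methods.Rmd`) explains the models, parameter
choices and limitations.

## Worked example

```r
library(candseq)

pool <- make_haplotype_pool(10000, 30, ld_rho = 0.95,
                            maf_range = c(0.1, 0.45), seed = 1)
spec <- cohort_spec(n_cases = 1000, n_controls = 1000, causal_index = 15,
                    odds_ratio = 1.4, prevalence = 0.1, seed = 2)
gm <- simulate_cohort(pool, spec)

res <- qc_filter(gm, qc_config())
assoc <- assoc_scan(res$genotypes)
assoc[order(assoc$p)[1:3], c("snp", "pos", "chi2", "p", "odds_ratio")]
#>         snp   pos chi2        p odds_ratio
#> 15 snp_0015 15000 43.0 5.50e-11       1.53
#> 13 snp_0013 13000 30.8 2.81e-08       1.44
#> 14 snp_0014 14000 26.7 2.32e-07       1.47

gene_test(assoc$chi2, ld_correlation_matrix(res$genotypes),
          n_sims = 1e5, seed = 3, gene = "geneA")
#> <gene_test_result> geneA: 30 SNPs, T = 340.184, empirical P = 1e-05 (100000 sims)

fits <- compare_candidates(res$genotypes, c("snp_0015", "snp_0020"),
                           include_candidate = TRUE)
fits[[1]]
#> <consistency_fit> candidate snp_0015: slope 6.444 (se 0.735), intercept 0.061 (se 0.367), 30 SNPs
fits[[2]]
#> <consistency_fit> candidate snp_0020: slope 4.018 (se 1.082), intercept 1.202 (se 0.545), 30 SNPs
```

The simulated causal SNP (`snp_0015`, per-allele OR 1.4) tops the
single-SNP scan (P = 5.5e-11, estimated allelic OR 1.53 vs 1.4 simulated
on slightly different scales), the gene containing it is flagged by the
LD-aware gene test (empirical P = 1e-05, the resolution floor of 10⁵
simulations), and the consistency fit ranks it above a five-SNP-distant
competitor: its slope (6.44) approximates its own |Z| while the
competitor's line is shallower with an inflated intercept — the
signature of a proxy rather than the causal variant.

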