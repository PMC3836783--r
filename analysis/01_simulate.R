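#!/usr/bin/env Rscript
# Stage 1: simulate the study system.
#
# Builds an LD-structured haplotype pool for a three-gene candidate
# region, draws a case-control cohort under a logistic disease model with
# one causal SNP, injects realistic genotype missingness, and sequences a
# 50-control discovery panel as per-sample pileups. Writes PED/MAP, BED
# regions and pileup TSVs under results/data/.

suppressPackageStartupMessages(library(candseq))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
set.seed(1)

n_snps <- 150
# strong local LD (latent AR(1) rho 0.95) emulates the tight block
# structure of a candidate-gene region
pool <- make_haplotype_pool(20000, n_snps, ld_rho = 0.95,
                            maf_range = c(0.05, 0.45), seed = 11)
spec <- cohort_spec(n_cases = 1738, n_controls = 1802, causal_index = 75,
                    odds_ratio = 1.3, prevalence = 0.1, seed = 12)
gm <- simulate_cohort(pool, spec)
gm <- inject_missingness(gm, snp_rate = 0.02, sample_rate = 0.02, seed = 13)
write_ped_map(gm, "results/data/cohort")

# three "genes" partition the region; BED is 0-based half-open
m <- ncol(gm$genotypes)
cuts <- round(seq(0, m, length.out = 4))
regions <- data.frame(
  chrom = "1",
  start = gm$map$pos[cuts[1:3] + 1] - 1000,
  end = gm$map$pos[cuts[2:4]],
  name = c("geneA", "geneB", "geneC"))
write_bed(regions, "results/data/genes.bed")

# discovery panel: 50 controls, sequenced at ~30x with 1% error
disc <- which(gm$phenotype == 0)[1:50]
pile <- simulate_pileups(gm_subset(gm, samples = disc), mean_depth = 30,
                         error_rate = 0.01, seed = 14)
write_pileup(pile, "results/data/discovery_pileups.tsv")

cat(sprintf("cohort: %d cases + %d controls x %d SNPs (%.2f%% missing)\n",
            sum(gm$phenotype == 1), sum(gm$phenotype == 0), m,
            100 * mean(is.na(gm$genotypes))))
cat(sprintf("discovery panel: %d samples, %d pileup rows\n",
            length(disc), nrow(pile)))
cat("wrote results/data/{cohort.ped,cohort.map,genes.bed,discovery_pileups.tsv}\n")
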