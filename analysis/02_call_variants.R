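#!/usr/bin/env Rscript
# Stage 2: per-sample SNP calling on the discovery panel.
#
# Applies the threshold caller (minimum 20x, per-sample theoretical
# maximum coverage, 35% alternative-read fraction for a heterozygote) to
# each discovery sample, merges the calls into a cohort site list with
# allele frequencies, summarizes coverage per gene region, and writes a
# merged VCF.

suppressPackageStartupMessages(library(candseq))
dir.create("results", showWarnings = FALSE)

pile <- read_pileup("results/data/discovery_pileups.tsv")
regions <- read_bed("results/data/genes.bed")

on_target <- 0.27  # fraction of reads mapping back to the region
calls <- do.call(rbind, lapply(unique(pile$sample), function(s) {
  p <- pile[pile$sample == s, , drop = FALSE]
  n_reads <- sum(p$depth) / 50 / on_target
  cfg <- caller_config(
    min_coverage = 20,
    max_coverage = max_coverage_threshold(n_reads, 50, nrow(p)))
  call_sample_variants(p, cfg)
}))
merged <- merge_calls(calls, pile, min_coverage = 20)
write_vcf(merged, "results/called_sites.vcf")

# the assay tiles SNP sites rather than every bp of the gene regions, so
# summarize depth over assayed sites: one 1-bp interval per site, then
# aggregate per gene
site_regions <- data.frame(chrom = "1",
                           start = sort(unique(pile$pos)) - 1,
                           end = sort(unique(pile$pos)))
site_regions$name <- regions$name[
  findInterval(site_regions$end, regions$start)]
per_site <- coverage_summary(pile, site_regions)
cov <- do.call(rbind, lapply(split(per_site, per_site$name), function(d)
  data.frame(name = d$name[1], n_sites = nrow(d),
             mean_depth = mean(d$mean_depth),
             pct_bp_ge_10x = mean(d$pct_bp_ge_10x),
             pct_bp_ge_20x = mean(d$pct_bp_ge_20x))))
write.table(cov, "results/coverage_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("%d per-sample calls -> %d merged sites\n",
            nrow(calls), nrow(merged)))
cat(sprintf("maf spectrum: %d sites < 5%%, %d in 5-10%%, %d > 10%%\n",
            sum(maf_bin(merged$maf) == "lt5"),
            sum(maf_bin(merged$maf) == "5to10"),
            sum(maf_bin(merged$maf) == "gt10")))
print(cov[, c("name", "mean_depth", "pct_bp_ge_10x", "pct_bp_ge_20x")])
cat("wrote results/called_sites.vcf, results/coverage_summary.tsv\n")
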