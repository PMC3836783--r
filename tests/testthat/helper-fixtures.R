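# Fixture builders shared across test files. Everything is generated in
# code so that truth is known exactly.

# genotype_matrix from explicit case/control dosage matrices
gm_from_dosages <- function(case_mat, ctrl_mat) {
  g <- rbind(as.matrix(case_mat), as.matrix(ctrl_mat))
  genotype_matrix(g, phenotype = rep(1:0, c(nrow(case_mat), nrow(ctrl_mat))))
}

# one-SNP cohort whose allele-count table is exactly
# (minor_ca, major_ca; minor_co, major_co); counts must be even-compatible
gm_one_snp_counts <- function(minor_ca, major_ca, minor_co, major_co) {
  build <- function(minor, major) {
    # express minor = 2*a + b: a hom-minor individuals, b heterozygotes
    n <- (minor + major) / 2
    a <- minor %/% 2; b <- minor - 2 * a
    c(rep(2L, a), rep(1L, b), rep(0L, n - a - b))
  }
  ca <- build(minor_ca, major_ca)
  co <- build(minor_co, major_co)
  gm_from_dosages(matrix(ca, ncol = 1), matrix(co, ncol = 1))
}

# pileup row constructor
pileup_row <- function(sample = "s1", chrom = "1", pos = 100, ref = "A",
                       counts = c(A = 0, C = 0, G = 0, T = 0)) {
  data.frame(sample = sample, chrom = chrom, pos = pos, ref = ref,
             depth = sum(counts), count_A = counts[["A"]],
             count_C = counts[["C"]], count_G = counts[["G"]],
             count_T = counts[["T"]], stringsAsFactors = FALSE)
}

# standard small LD cohort used by several files
small_ld_cohort <- function(n_cases = 400, n_controls = 400, n_snps = 12,
                            ld_rho = 0.9, odds_ratio = 1, causal = NULL,
                            seed = 42, maf_range = c(0.15, 0.45)) {
  pool <- make_haplotype_pool(4000, n_snps, ld_rho, maf_range, seed = seed)
  spec <- cohort_spec(n_cases, n_controls, causal_index = causal,
                      odds_ratio = odds_ratio, prevalence = 0.3,
                      seed = seed + 1)
  simulate_cohort(pool, spec)
}
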