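test_that("haplotype pool respects target mafs and positions", {
  pool <- make_haplotype_pool(50000, 30, ld_rho = 0.5,
                              maf_range = c(0.05, 0.5), seed = 7)
  realized <- colMeans(pool$haplotypes)
  expect_true(all(abs(realized - pool$target_mafs) < 0.01))
  expect_true(all(diff(pool$positions) > 0))
  counts <- colSums(pool$haplotypes)
  expect_true(all(counts > 0 & counts < nrow(pool$haplotypes)))
})

test_that("adjacent r2 tracks the latent AR(1) correlation", {
  r2_adj <- function(pool) {
    h <- pool$haplotypes
    mean(vapply(seq_len(ncol(h) - 1), function(j)
      suppressWarnings(stats::cor(h[, j], h[, j + 1]))^2, numeric(1)),
      na.rm = TRUE)
  }
  p0 <- make_haplotype_pool(20000, 20, ld_rho = 0, seed = 1)
  expect_lt(r2_adj(p0), 0.005)

  p99 <- make_haplotype_pool(20000, 2, ld_rho = 0.99,
                             maf_range = c(0.3, 0.3), seed = 2)
  # comonotone limit: the tetrachoric model at rho = 0.99, matched mafs
  orthant <- function(t, rho) {
    stats::integrate(function(x)
      stats::dnorm(x) * stats::pnorm((t - rho * x) / sqrt(1 - rho^2),
                                     lower.tail = FALSE),
      lower = t, upper = Inf, rel.tol = 1e-10)$value
  }
  t3 <- qnorm(1 - 0.3)
  r2_the <- (orthant(t3, 0.99) - 0.09)^2 / (0.3 * 0.7)^2
  expect_gt(r2_the, 0.8)  # the limit itself approaches 1
  expect_lt(abs(r2_adj(p99) - r2_the), 0.03)

  p5 <- make_haplotype_pool(20000, 20, ld_rho = 0.5, seed = 3)
  expect_true(r2_adj(p0) < r2_adj(p5) && r2_adj(p5) < r2_adj(p99))
})

test_that("adjacent r2 matches the bivariate-normal orthant oracle", {
  # oracle: P(Z1 > t, Z2 > t) under correlation rho by numeric integration
  orthant <- function(t, rho) {
    stats::integrate(function(x)
      stats::dnorm(x) * stats::pnorm((t - rho * x) / sqrt(1 - rho^2),
                                     lower.tail = FALSE),
      lower = t, upper = Inf, rel.tol = 1e-10)$value
  }
  m <- 0.3; rho <- 0.9
  t <- qnorm(1 - m)
  p11 <- orthant(t, rho)
  D <- p11 - m^2
  r2_expected <- D^2 / (m * (1 - m))^2

  pool <- make_haplotype_pool(50000, 10, ld_rho = rho,
                              maf_range = c(m, m), seed = 8)
  h <- pool$haplotypes
  r2_emp <- mean(vapply(seq_len(ncol(h) - 1), function(j)
    stats::cor(h[, j], h[, j + 1])^2, numeric(1)))
  expect_lt(abs(r2_emp - r2_expected), 0.02)
})

test_that("pool argument validation", {
  expect_error(make_haplotype_pool(100, 1), "n_snps")
  expect_error(make_haplotype_pool(100, 5, maf_range = c(0, 0.5)), "maf_range")
  expect_error(make_haplotype_pool(100, 5, ld_rho = 1), "ld_rho")
})

test_that("null cohort has equal case/control allele frequencies", {
  gm <- small_ld_cohort(n_cases = 1000, n_controls = 1000, n_snps = 20,
                        odds_ratio = 1, seed = 10)
  ca <- gm$genotypes[gm$phenotype == 1, ]
  co <- gm$genotypes[gm$phenotype == 0, ]
  diffs <- abs(colMeans(ca) / 2 - colMeans(co) / 2)
  expect_lt(max(diffs), 0.06)  # ~4 binomial SDs at n = 1000/group
})

test_that("simulated allelic odds ratio is recovered within its 95% CI", {
  pool <- make_haplotype_pool(20000, 10, ld_rho = 0,
                              maf_range = c(0.3, 0.3), seed = 21)
  spec <- cohort_spec(2000, 2000, causal_index = 5, odds_ratio = 2,
                      prevalence = 0.1, seed = 22)
  gm <- simulate_cohort(pool, spec)
  a <- sum(gm$genotypes[gm$phenotype == 1, 5]); b <- 2 * 2000 - a
  c_ <- sum(gm$genotypes[gm$phenotype == 0, 5]); d <- 2 * 2000 - c_
  lor <- log(a * d / (b * c_))
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  expect_true(abs(lor - log(2)) < 1.96 * se)
})

test_that("cohort simulation is reproducible and exactly sized", {
  pool <- make_haplotype_pool(2000, 8, seed = 30)
  spec <- cohort_spec(120, 80, causal_index = 3, odds_ratio = 1.4,
                      prevalence = 0.2, seed = 31)
  gm1 <- simulate_cohort(pool, spec)
  gm2 <- simulate_cohort(pool, spec)
  expect_identical(gm1, gm2)
  expect_equal(sum(gm1$phenotype == 1), 120)
  expect_equal(sum(gm1$phenotype == 0), 80)
})

test_that("unattainable case quota fails loudly with a diagnostic", {
  pool <- make_haplotype_pool(2000, 5, seed = 33)
  spec <- cohort_spec(500, 10, odds_ratio = 1, prevalence = 1e-4, seed = 34)
  expect_error(simulate_cohort(pool, spec, max_draws = 2e4),
               class = "candseq_generation_failure")
})

test_that("pileup generator is noise-free at error rate 0", {
  gm <- genotype_matrix(matrix(0L, 5, 20))
  p <- simulate_pileups(gm, mean_depth = 30, error_rate = 0, seed = 40)
  alt <- p$count_C  # a1 is "C" by default
  expect_true(all(alt == 0))
  expect_true(all(p$count_A == p$depth))
})

test_that("heterozygote pileups have mean alt fraction near one half", {
  gm <- genotype_matrix(matrix(1L, 10, 200))
  p <- simulate_pileups(gm, mean_depth = 30, error_rate = 0, seed = 41)
  frac <- p$count_C[p$depth > 0] / p$depth[p$depth > 0]
  expect_lt(abs(mean(frac) - 0.5), 0.005)
})

test_that("hom-alt alt counts match Binomial(depth, 1 - error) exactly", {
  # randomized PIT: u = F(x-1) + U * f(x) is Uniform(0,1) iff x ~ Binom
  gm <- genotype_matrix(matrix(2L, 10, 1000))
  p <- simulate_pileups(gm, mean_depth = 30, error_rate = 0.01, seed = 42)
  keep <- p$depth > 0
  x <- p$count_C[keep]; n <- p$depth[keep]
  set.seed(43)
  u <- pbinom(x - 1, n, 0.99) + runif(length(x)) * dbinom(x, n, 0.99)
  ks <- suppressWarnings(ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("pileup error rate validation", {
  gm <- genotype_matrix(matrix(1L, 2, 2))
  expect_error(simulate_pileups(gm, error_rate = 0.5), "error_rate")
})

test_that("missingness injection: identity at zero, targeted rates bite", {
  gm <- small_ld_cohort(n_cases = 300, n_controls = 300, n_snps = 10, seed = 50)
  expect_identical(inject_missingness(gm, 0, 0), gm)

  gm1 <- inject_missingness(gm, snp_rate = 0.3, snps = 4, seed = 51)
  fr <- mean(is.na(gm1$genotypes[, 4]))
  expect_gt(fr, 0.10)  # designated SNP now fails the >10% filter
  res <- qc_filter(gm1)
  expect_true(colnames(gm$genotypes)[4] %in%
                res$report$id[res$report$step == 2])

  gm2 <- inject_missingness(gm, sample_rate = 0.35, samples = 7, seed = 52)
  expect_gt(mean(is.na(gm2$genotypes[7, ])), 0.25)
  res2 <- qc_filter(gm2)
  expect_true(rownames(gm$genotypes)[7] %in%
                res2$report$id[res2$report$step == 1])
})

test_that("realized missingness approximates requested rates", {
  gm <- genotype_matrix(matrix(1L, 400, 50))
  out <- inject_missingness(gm, snp_rate = 0.1, sample_rate = 0.05, seed = 60)
  overall <- mean(is.na(out$genotypes))
  expected <- 1 - (1 - 0.1) * (1 - 0.05)
  expect_lt(abs(overall - expected), 0.01)
})
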