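test_that("null Z-scores are empirically standard normal", {
  pool <- make_haplotype_pool(6000, 400, ld_rho = 0,
                              maf_range = c(0.1, 0.5), seed = 240)
  spec <- cohort_spec(600, 600, odds_ratio = 1, prevalence = 0.5, seed = 241)
  gm <- simulate_cohort(pool, spec)
  zt <- per_snp_logistic_z(gm)
  z <- zt$z[zt$estimable]
  expect_gt(length(z), 350)
  expect_lt(abs(mean(z)), 0.15)
  expect_true(var(z) > 0.8 && var(z) < 1.2)
})

test_that("logistic Wald z matches a likelihood-grid oracle expectation", {
  # oracle: expected Wald z at the true model, from expected genotype-cell
  # counts via grid maximisation of the binomial log-likelihood and a
  # numerical Hessian -- no IRLS involved
  n <- 4000; maf <- 0.3; b0 <- -0.5; b1 <- 0.5
  p_g <- dbinom(0:2, 2, maf)
  p_case <- plogis(b0 + b1 * (0:2))
  e_case <- n * p_g * p_case
  e_ctrl <- n * p_g * (1 - p_case)
  ll <- function(th) sum(e_case * plogis(th[1] + th[2] * (0:2), log.p = TRUE) +
                           e_ctrl * plogis(th[1] + th[2] * (0:2),
                                           lower.tail = FALSE, log.p = TRUE))
  grid <- expand.grid(a = seq(-1, 0, by = 0.002), b = seq(0, 1, by = 0.002))
  best <- grid[which.max(apply(grid, 1, ll)), ]
  h <- 1e-4
  d2 <- (ll(c(best$a, best$b + h)) - 2 * ll(c(best$a, best$b)) +
           ll(c(best$a, best$b - h))) / h^2
  # profile out the intercept via the full 2x2 information matrix
  daa <- (ll(c(best$a + h, best$b)) - 2 * ll(unlist(best)) +
            ll(c(best$a - h, best$b))) / h^2
  dab <- (ll(c(best$a + h, best$b + h)) - ll(c(best$a + h, best$b - h)) -
            ll(c(best$a - h, best$b + h)) + ll(c(best$a - h, best$b - h))) /
    (4 * h^2)
  info <- -matrix(c(daa, dab, dab, d2), 2)
  se_b <- sqrt(solve(info)[2, 2])
  z_expected <- best$b / se_b

  set.seed(242)
  g <- rbinom(n, 2, maf)
  y <- rbinom(n, 1, plogis(b0 + b1 * g))
  gm <- genotype_matrix(matrix(g, ncol = 1), phenotype = y)
  zt <- per_snp_logistic_z(gm)
  expect_true(zt$estimable)
  expect_lt(abs(zt$z - z_expected), 3)
})

test_that("monomorphic and separated SNPs are not estimable", {
  g <- cbind(mono = rep(1L, 100), sep = rep(0:1, each = 50))
  gm <- genotype_matrix(g, phenotype = rep(0:1, each = 50))
  zt <- per_snp_logistic_z(gm)
  expect_false(zt$estimable[1])
  expect_false(zt$estimable[2])  # perfect separation
})

test_that("consistency fit reproduces hand OLS and its edge cases", {
  # collinear points: slope 4, intercept 1 exactly
  z <- c(s1 = 1, s2 = 3, s3 = 5)
  r2 <- c(0, 0.25, 1)
  f <- suppressWarnings(consistency_fit(z, r2))  # exact fit warns in summary
  expect_equal(f$slope, 4.0, tolerance = 1e-12)
  expect_equal(f$intercept, 1.0, tolerance = 1e-12)

  # constant response: slope exactly 0
  f0 <- suppressWarnings(
    consistency_fit(c(a = 2, b = -2, c = 2, d = 2), c(0, 0.3, 0.6, 1)))
  expect_equal(f0$slope, 0, tolerance = 1e-12)

  expect_error(consistency_fit(c(1, 2), c(0, 1)), "3 points")
  expect_error(consistency_fit(c(1, 2, 3), c(0, 0.5, 2)), "r2")
})

test_that("fit is invariant to point order and z sign flips", {
  set.seed(243)
  z <- rnorm(10); r2 <- runif(10)
  names(z) <- paste0("s", 1:10)
  f1 <- consistency_fit(z, r2)
  perm <- sample(10)
  f2 <- consistency_fit(z[perm], r2[perm])
  f3 <- consistency_fit(-z, r2)
  expect_equal(f1$slope, f2$slope, tolerance = 1e-12)
  expect_equal(f1$slope, f3$slope, tolerance = 1e-12)
})

test_that("candidate's own point is excluded unless requested", {
  z <- c(cand = 5, s1 = 1, s2 = 2, s3 = 3)
  r2 <- c(1, 0.1, 0.4, 0.8)
  f_out <- consistency_fit(z, r2, candidate = "cand")
  expect_equal(f_out$n_snps, 3)
  f_in <- consistency_fit(z, r2, candidate = "cand",
                          include_candidate = TRUE)
  expect_equal(f_in$n_snps, 4)
})

test_that("null cohorts give mean slope consistent with zero", {
  pool <- make_haplotype_pool(6000, 40, ld_rho = 0.9,
                              maf_range = c(0.05, 0.5), seed = 250)
  cand <- colnames(pool$haplotypes)[20]
  reps <- 150
  slopes <- vapply(seq_len(reps), function(i) {
    spec <- cohort_spec(800, 800, odds_ratio = 1, prevalence = 0.5,
                        seed = 250 + i)
    gm <- simulate_cohort(pool, spec)
    compare_candidates(gm, cand)[[1]]$slope
  }, numeric(1))
  ci_half <- 2.576 * sd(slopes) / sqrt(reps)
  expect_lt(abs(mean(slopes)), ci_half)
})

test_that("a causal SNP's slope approximates its own |Z| and beats a proxy", {
  # effect sized for marginal |Z| near 5 at 2000+2000, in a window of
  # strong decaying LD (adjacent indicator correlation ~0.9). Each
  # candidate's own (r = 1, |Z|) point anchors its fit; under the model
  # E|Z_j| = r_jc |Z_c| the fit against the causal SNP recovers |Z_c|
  # while a moderate-LD proxy's line is pulled down by the off-proxy arm
  pool <- make_haplotype_pool(8000, 30, ld_rho = 0.99,
                              maf_range = c(0.3, 0.3), seed = 260)
  ci <- 15
  cand <- colnames(pool$haplotypes)[ci]
  # proxy: the window SNP whose pool r2 with the candidate is nearest 0.5
  h <- pool$haplotypes
  r2_pool <- vapply(seq_len(ncol(h)), function(j)
    cor(h[, ci], h[, j])^2, numeric(1))
  proxy_idx <- setdiff(order(abs(r2_pool - 0.5)), ci)[1]
  proxy <- colnames(h)[proxy_idx]
  expect_true(abs(r2_pool[proxy_idx] - 0.5) < 0.25)

  reps <- 8
  res <- vapply(seq_len(reps), function(i) {
    spec <- cohort_spec(2000, 2000, causal_index = ci, odds_ratio = 1.28,
                        prevalence = 0.1, seed = 260 + i)
    gm <- simulate_cohort(pool, spec)
    zt <- per_snp_logistic_z(gm)
    z_cand <- abs(zt$z[zt$snp == cand])
    fits <- compare_candidates(gm, c(cand, proxy), include_candidate = TRUE)
    c(z_cand, fits[[cand]]$slope, fits[[proxy]]$slope)
  }, numeric(3))
  mean_z <- mean(res[1, ]); mean_slope <- mean(res[2, ])
  expect_lt(abs(mean_slope - mean_z) / mean_z, 0.15)
  expect_gt(mean(res[2, ] - res[3, ]), 0)  # candidate beats its proxy
})

test_that("single candidate reduces to one consistency fit", {
  gm <- small_ld_cohort(n_cases = 300, n_controls = 300, n_snps = 8,
                        seed = 270)
  cand <- colnames(gm$genotypes)[4]
  fits <- compare_candidates(gm, cand)
  expect_equal(length(fits), 1)
  expect_s3_class(fits[[1]], "consistency_fit")
  expect_equal(fits[[1]]$candidate, cand)
  expect_error(compare_candidates(gm, "absent_snp"), "within the window")
})
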