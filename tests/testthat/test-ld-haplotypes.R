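test_that("EM recovers unambiguous-phase haplotype frequencies", {
  geno <- rbind(matrix(2L, 50, 2), matrix(0L, 50, 2))
  f <- em_haplotype_freqs(geno)
  expect_equal(unname(f["11"]), 0.5, tolerance = 1e-8)
  expect_equal(unname(f["00"]), 0.5, tolerance = 1e-8)
})

test_that("a lone double heterozygote lands on the uniform fixed point", {
  f <- em_haplotype_freqs(matrix(1L, 1, 2))
  expect_equal(unname(sort(f)), rep(0.25, 4), tolerance = 1e-8)
})

test_that("EM frequencies converge to true pool frequencies", {
  # pair the pool's 4000 haplotypes exhaustively into 2000 individuals so
  # the cohort's haplotype distribution IS the pool distribution: the only
  # estimation error left is phase ambiguity
  pool <- make_haplotype_pool(4000, 4, ld_rho = 0.8,
                              maf_range = c(0.2, 0.4), seed = 140)
  h <- pool$haplotypes
  geno <- h[seq(1, 3999, by = 2), ] + h[seq(2, 4000, by = 2), ]
  f <- em_haplotype_freqs(geno)
  truth <- table(apply(h, 1, paste, collapse = "")) / nrow(h)
  for (hap in names(f)) {
    t_h <- if (hap %in% names(truth)) unname(truth[hap]) else 0
    expect_lt(abs(unname(f[hap]) - t_h), 0.01)
  }
})

test_that("EM log-likelihood is non-decreasing every iteration", {
  for (s in 1:5) {
    gm <- small_ld_cohort(n_cases = 100, n_controls = 100, n_snps = 4,
                          seed = 150 + s)
    f <- em_haplotype_freqs(gm$genotypes)
    ll <- attr(f, "loglik")
    expect_true(all(diff(ll) > -1e-8))
    expect_true(attr(f, "converged"))
    expect_equal(sum(f), 1, tolerance = 1e-9)
  }
})

test_that("EM input guards", {
  expect_error(em_haplotype_freqs(matrix(1L, 5, 1)), "at least 2")
  expect_error(em_haplotype_freqs(matrix(1L, 5, 9)), "max_snps")
})

test_that("duplicated SNP columns give complete LD", {
  gm <- small_ld_cohort(n_cases = 200, n_controls = 200, n_snps = 4,
                        seed = 160)
  g <- cbind(gm$genotypes[, 1], gm$genotypes[, 1])
  colnames(g) <- c("a", "b")
  r <- ld_stats(g, 1, 2)
  expect_equal(r$r2, 1, tolerance = 1e-6)
  expect_equal(r$D_prime, 1, tolerance = 1e-6)
})

test_that("independent SNPs show near-zero r2", {
  pool <- make_haplotype_pool(10000, 6, ld_rho = 0,
                              maf_range = c(0.2, 0.4), seed = 161)
  spec <- cohort_spec(2500, 2500, odds_ratio = 1, prevalence = 0.5,
                      seed = 162)
  gm <- simulate_cohort(pool, spec)
  r <- ld_stats(gm, 1, 4)
  expect_lt(r$r2, 0.01)
})

test_that("LD statistics match hand arithmetic on unambiguous phase", {
  # 20 AB/AB, 5 Ab/Ab, 5 aB/aB, 20 ab/ab individuals: no double hets,
  # haplotype counts are exact. pAB = .4, pA = pB = .5
  geno <- rbind(matrix(2L, 20, 2),
                cbind(rep(2L, 5), rep(0L, 5)),
                cbind(rep(0L, 5), rep(2L, 5)),
                matrix(0L, 20, 2))
  r <- ld_stats(geno, 1, 2)
  expect_equal(r$D, 0.15, tolerance = 1e-8)
  expect_equal(r$D_prime, 0.6, tolerance = 1e-8)
  expect_equal(r$r2, 0.36, tolerance = 1e-8)
})

test_that("r2 on phased haplotypes equals squared indicator correlation", {
  pool <- make_haplotype_pool(3000, 6, ld_rho = 0.8, seed = 163)
  h <- pool$haplotypes
  for (j in 1:5) {
    # each haplotype as a homozygous diploid: no hets, EM is exact
    r <- ld_stats(2L * h, j, j + 1, ci = FALSE)
    expect_equal(r$r2, stats::cor(h[, j], h[, j + 1])^2, tolerance = 1e-6)
  }
})

test_that("monomorphic input is flagged undefined", {
  g <- cbind(rep(0L, 50), rbinom(50, 2, 0.4))
  r <- ld_stats(g, 1, 2)
  expect_true(r$undefined)
})

test_that("blocks from synthetic CI patterns follow the Gabriel rule", {
  mk_pairs <- function(k, ci_low, ci_high) {
    idx <- t(combn(k, 2))
    data.frame(i = idx[, 1], j = idx[, 2], ci_low = ci_low,
               ci_high = ci_high, r2 = 0.9)
  }
  # all pairs strong with tight CIs: one block spanning everything
  strong <- mk_pairs(5, 0.9, 1.0)
  b <- build_blocks(strong, 5)
  expect_equal(length(b), 1)
  expect_equal(b[[1]]$snps, 1:5)
  # all pairs wide-open CIs (recombination evidence): no blocks
  weak <- mk_pairs(5, 0.0, 0.5)
  expect_equal(length(b <- build_blocks(weak, 5)), 0)
})

test_that("block construction matches a brute-force rule oracle", {
  gm <- small_ld_cohort(n_cases = 500, n_controls = 500, n_snps = 20,
                        ld_rho = 0.95, seed = 170, maf_range = c(0.2, 0.4))
  lp <- ld_matrix(gm)
  blocks <- build_blocks(lp, 20, positions = gm$map$pos)

  # oracle: re-apply the definition by exhaustive enumeration
  strong <- matrix(FALSE, 20, 20); inform <- matrix(FALSE, 20, 20)
  for (r in seq_len(nrow(lp))) {
    s <- lp$ci_low[r] >= 0.70 && lp$ci_high[r] >= 0.98
    rec <- lp$ci_high[r] < 0.90
    strong[lp$i[r], lp$j[r]] <- s
    inform[lp$i[r], lp$j[r]] <- s || rec
  }
  spans <- list()
  for (i in 1:19) for (j in (i + 1):20) {
    if (!strong[i, j]) next
    ii <- i:j
    ns <- sum(strong[ii, ii][upper.tri(diag(length(ii)))])
    ni <- sum(inform[ii, ii][upper.tri(diag(length(ii)))])
    if (ni > 0 && ns / ni >= 0.95) spans[[length(spans) + 1]] <- c(i, j)
  }
  lens <- vapply(spans, function(x) x[2] - x[1], numeric(1))
  spans <- spans[order(-lens, vapply(spans, `[`, numeric(1), 1))]
  used <- rep(FALSE, 20); oracle <- list()
  for (sp in spans) {
    if (any(used[sp[1]:sp[2]])) next
    used[sp[1]:sp[2]] <- TRUE
    oracle[[length(oracle) + 1]] <- sp
  }
  oracle <- oracle[order(vapply(oracle, `[`, numeric(1), 1))]
  expect_equal(length(blocks), length(oracle))
  for (k in seq_along(blocks)) {
    expect_equal(blocks[[k]]$start, oracle[[k]][1])
    expect_equal(blocks[[k]]$end, oracle[[k]][2])
  }
  # blocks are disjoint and ordered
  if (length(blocks) > 1) {
    starts <- vapply(blocks, `[[`, numeric(1), "start")
    ends <- vapply(blocks, `[[`, numeric(1), "end")
    expect_true(all(diff(starts) > 0))
    expect_true(all(starts[-1] > ends[-length(ends)]))
  }
})

test_that("unsorted positions are rejected and the r2 floor drops SNPs", {
  lp <- data.frame(i = 1, j = 2, ci_low = 0.9, ci_high = 1, r2 = 0.1)
  expect_error(build_blocks(lp, 2, positions = c(200, 100)), "ordered")
  # both SNPs fall below the floor: no blocks possible
  expect_equal(length(build_blocks(lp, 2, r2_floor = 0.2)), 0)
})

test_that("haplotype association on hand-counted unambiguous data", {
  # single-SNP block must reduce to the allelic test
  gm <- gm_one_snp_counts(60, 40, 40, 60)
  h <- haplotype_association(gm, 1)
  expect_equal(h$block_p, pchisq(8, 1, lower.tail = FALSE))

  # identical case/control genotype sets: all haplotype tests null
  geno <- rbind(matrix(2L, 30, 2), matrix(0L, 30, 2),
                cbind(rep(2L, 10), rep(0L, 10)))
  gm2 <- gm_from_dosages(geno, geno)
  h2 <- haplotype_association(gm2, 1:2)
  expect_true(all(h2$table$p > 0.9999))
  expect_equal(max(h2$table$chi2), 0, tolerance = 1e-10)
})

test_that("two-SNP haplotype test mirrors the allelic arithmetic", {
  # haplotype counts: cases (60, 40), controls (40, 60) on hap "11" vs
  # rest; individuals built from identical haplotype pairs so EM is exact
  build <- function(n11) {
    rbind(matrix(2L, n11 / 2, 2), matrix(0L, (100 - n11) / 2, 2))
  }
  gm <- gm_from_dosages(build(60), build(40))
  h <- haplotype_association(gm, 1:2)
  row <- h$table[h$table$haplotype == "11", ]
  expect_equal(row$chi2, 8.0, tolerance = 1e-6)
})

test_that("rare haplotypes are pooled before testing", {
  # hap "10" occurs once in 100 individuals (freq 0.005 < 0.01)
  geno <- rbind(matrix(2L, 40, 2), matrix(0L, 59, 2),
                matrix(c(2L, 0L), 1, 2))
  gm <- gm_from_dosages(geno, rbind(matrix(2L, 40, 2), matrix(0L, 60, 2)))
  h <- haplotype_association(gm, 1:2)
  expect_true("rare" %in% h$table$haplotype)
  expect_false("10" %in% h$table$haplotype)
})
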