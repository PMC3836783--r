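#' Generate an LD-structured haplotype pool
#'
#' Haplotypes are drawn through a Gaussian copula: a latent standard normal
#' field with first-order autoregressive correlation `ld_rho^|i-j|` between
#' SNP columns is thresholded per column at the quantile matching a minor
#' allele frequency drawn uniformly from `maf_range`. Adjacent-SNP r-squared
#' therefore increases monotonically (in expectation) with `ld_rho`, and the
#' implied two-SNP distribution has a closed tetrachoric form usable as an
#' oracle. Columns that come out monomorphic are dropped with a warning so
#' a fixed seed always reproduces the same pool.
#'
#' @param n_haplotypes number of haplotypes to draw.
#' @param n_snps number of SNP columns before the monomorphic drop.
#' @param ld_rho AR(1) latent correlation in `[0, 1)`.
#' @param maf_range length-2 interval within `(0, 0.5]` from which per-SNP
#'   target minor allele frequencies are drawn.
#' @param positions_step spacing in bp between consecutive SNPs.
#' @param seed optional integer seed.
#' @return an object of class `haplotype_pool`: list with `haplotypes`
#'   (0/1 matrix, haplotypes x SNPs), `positions` (bp, strictly increasing)
#'   and `target_mafs`.
#' @export
make_haplotype_pool <- function(n_haplotypes, n_snps, ld_rho = 0.8,
                                maf_range = c(0.05, 0.5),
                                positions_step = 1000, seed = NULL) {
  if (n_snps < 2) stop("n_snps must be at least 2")
  if (n_haplotypes < 2) stop("n_haplotypes must be at least 2")
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must lie in [0, 1)")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (!is.null(seed)) set.seed(seed)

  mafs <- stats::runif(n_snps, maf_range[1], maf_range[2])
  z <- matrix(0, n_haplotypes, n_snps)
  z[, 1] <- stats::rnorm(n_haplotypes)
  if (n_snps > 1) {
    innov_sd <- sqrt(1 - ld_rho^2)
    for (j in 2:n_snps)
      z[, j] <- ld_rho * z[, j - 1] + stats::rnorm(n_haplotypes, sd = innov_sd)
  }
  thr <- stats::qnorm(1 - mafs)
  hap <- matrix(0L, n_haplotypes, n_snps)
  hap[z > matrix(thr, n_haplotypes, n_snps, byrow = TRUE)] <- 1L

  counts <- colSums(hap)
  keep <- counts > 0L & counts < n_haplotypes
  if (!all(keep))
    warning(sprintf("dropped %d monomorphic simulated column(s)", sum(!keep)))
  hap <- hap[, keep, drop = FALSE]
  positions <- as.integer(positions_step * seq_len(n_snps))[keep]
  colnames(hap) <- sprintf("snp_%04d", which(keep))
  structure(list(haplotypes = hap, positions = positions,
                 target_mafs = mafs[keep]),
            class = "haplotype_pool")
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat(sprintf("<haplotype_pool> %d haplotypes x %d SNPs, maf %.3f-%.3f\n",
              nrow(x$haplotypes), ncol(x$haplotypes),
              min(x$target_mafs), max(x$target_mafs)))
  invisible(x)
}

#' Case-control cohort design
#'
#' @param n_cases,n_controls target sample counts.
#' @param causal_index column index of the causal SNP in the pool, or
#'   `NULL` for a null cohort.
#' @param odds_ratio multiplicative per-allele odds ratio (> 0).
#' @param prevalence baseline disease probability at genotype 0, in (0, 1).
#' @param seed optional integer seed used by [simulate_cohort()].
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases, n_controls, causal_index = NULL,
                        odds_ratio = 1, prevalence = 0.1, seed = NULL) {
  if (odds_ratio <= 0) stop("odds_ratio must be > 0")
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must lie in (0, 1)")
  if (n_cases < 1 || n_controls < 1) stop("need at least one case and control")
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 causal_index = causal_index, odds_ratio = odds_ratio,
                 prevalence = prevalence, seed = seed),
            class = "cohort_spec")
}

#' Simulate a diploid case-control cohort from a haplotype pool
#'
#' Individuals are formed by sampling haplotype pairs with replacement;
#' disease status follows a logistic model
#' `logit P(case) = logit(prevalence) + log(odds_ratio) * g_causal`, and
#' rejection sampling continues until exactly `n_cases` cases and
#' `n_controls` controls have been accepted. With `odds_ratio = 1` (or no
#' causal SNP) phenotype is independent of genotype.
#'
#' @param pool a `haplotype_pool`.
#' @param spec a `cohort_spec`.
#' @param max_draws rejection-sampling cap; exceeding it raises a
#'   `candseq_generation_failure` error with a diagnostic.
#' @return a [genotype_matrix()] with cases first, then controls. The
#'   counted allele (`a1`) is the copula minor allele "C"; `a2` is "A".
#' @export
simulate_cohort <- function(pool, spec, max_draws = 1e7) {
  stopifnot(inherits(pool, "haplotype_pool"), inherits(spec, "cohort_spec"))
  m <- ncol(pool$haplotypes)
  n_hap <- nrow(pool$haplotypes)
  ci <- spec$causal_index
  if (!is.null(ci) && (ci < 1 || ci > m))
    stop("causal_index out of range")
  if (!is.null(spec$seed)) set.seed(spec$seed)

  alpha <- stats::qlogis(spec$prevalence)
  beta <- log(spec$odds_ratio)
  need_ca <- spec$n_cases; need_co <- spec$n_controls
  got_ca <- got_co <- 0L
  ca_idx <- matrix(0L, need_ca, 2)
  co_idx <- matrix(0L, need_co, 2)
  drawn <- 0
  batch <- max(1000L, 2L * (need_ca + need_co))
  while (got_ca < need_ca || got_co < need_co) {
    if (drawn >= max_draws)
      stop_generation_failure(
        "rejection sampling stalled after %d draws (have %d/%d cases, %d/%d controls); prevalence %.3g may be unattainable",
        drawn, got_ca, need_ca, got_co, need_co, spec$prevalence)
    i1 <- sample.int(n_hap, batch, replace = TRUE)
    i2 <- sample.int(n_hap, batch, replace = TRUE)
    g_causal <- if (is.null(ci)) rep(0L, batch) else
      pool$haplotypes[i1, ci] + pool$haplotypes[i2, ci]
    p <- stats::plogis(alpha + beta * g_causal)
    is_case <- stats::runif(batch) < p
    drawn <- drawn + batch
    take_ca <- which(is_case)[seq_len(min(sum(is_case), need_ca - got_ca))]
    take_co <- which(!is_case)[seq_len(min(sum(!is_case), need_co - got_co))]
    if (length(take_ca)) {
      rows <- got_ca + seq_along(take_ca)
      ca_idx[rows, ] <- cbind(i1[take_ca], i2[take_ca])
      got_ca <- got_ca + length(take_ca)
    }
    if (length(take_co)) {
      rows <- got_co + seq_along(take_co)
      co_idx[rows, ] <- cbind(i1[take_co], i2[take_co])
      got_co <- got_co + length(take_co)
    }
  }
  idx <- rbind(ca_idx, co_idx)
  geno <- pool$haplotypes[idx[, 1], , drop = FALSE] +
    pool$haplotypes[idx[, 2], , drop = FALSE]
  rownames(geno) <- c(sprintf("case_%04d", seq_len(need_ca)),
                      sprintf("ctrl_%04d", seq_len(need_co)))
  map <- data.frame(chrom = "1", snp = colnames(pool$haplotypes),
                    pos = pool$positions, a1 = "C", a2 = "A",
                    stringsAsFactors = FALSE)
  genotype_matrix(geno, phenotype = rep(1:0, c(need_ca, need_co)), map = map)
}

#' Simulate per-sample sequencing pileups for a cohort
#'
#' Per-site depth is Poisson(`mean_depth`); the alternative-allele read
#' count is Binomial(depth, p) with p equal to `error_rate`, 0.5 and
#' `1 - error_rate` for dosages 0, 1 and 2. Sites with missing genotype are
#' emitted with depth 0 (not sequenced). Error reads are directed to the
#' site's alternative allele, so allele counts always sum to depth.
#'
#' @param gm a [genotype_matrix()].
#' @param mean_depth mean sequencing depth (reads).
#' @param error_rate per-read error fraction in `[0, 0.5)`.
#' @param read_length read length in bp, recorded as an attribute (used by
#'   [max_coverage_threshold()] at the calling stage).
#' @param seed optional integer seed.
#' @return data frame with columns `sample`, `chrom`, `pos`, `ref`,
#'   `depth`, `count_A`, `count_C`, `count_G`, `count_T`.
#' @export
simulate_pileups <- function(gm, mean_depth = 30, error_rate = 0.01,
                             read_length = 50, seed = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (error_rate < 0 || error_rate >= 0.5)
    stop("error_rate must lie in [0, 0.5)")
  if (!is.null(seed)) set.seed(seed)
  g <- gm$genotypes
  n <- nrow(g); m <- ncol(g)
  depth <- matrix(stats::rpois(n * m, mean_depth), n, m)
  depth[is.na(g)] <- 0L
  p_alt <- matrix(0, n, m)
  p_alt[!is.na(g) & g == 0L] <- error_rate
  p_alt[!is.na(g) & g == 1L] <- 0.5
  p_alt[!is.na(g) & g == 2L] <- 1 - error_rate
  alt <- matrix(stats::rbinom(n * m, as.vector(depth), as.vector(p_alt)), n, m)

  bases <- c("A", "C", "G", "T")
  ref <- gm$map$a2; altb <- gm$map$a1
  out <- data.frame(
    sample = rep(rownames(g), each = m),
    chrom = rep(gm$map$chrom, times = n),
    pos = rep(gm$map$pos, times = n),
    ref = rep(ref, times = n),
    depth = as.vector(t(depth)),
    count_A = 0L, count_C = 0L, count_G = 0L, count_T = 0L,
    stringsAsFactors = FALSE
  )
  cnt <- matrix(0L, nrow(out), 4, dimnames = list(NULL, bases))
  ref_col <- match(rep(ref, times = n), bases)
  alt_col <- match(rep(altb, times = n), bases)
  altv <- as.vector(t(alt)); depv <- as.vector(t(depth))
  cnt[cbind(seq_len(nrow(out)), ref_col)] <- depv - altv
  cnt[cbind(seq_len(nrow(out)), alt_col)] <-
    cnt[cbind(seq_len(nrow(out)), alt_col)] + altv
  out$count_A <- cnt[, "A"]; out$count_C <- cnt[, "C"]
  out$count_G <- cnt[, "G"]; out$count_T <- cnt[, "T"]
  attr(out, "read_length") <- read_length
  attr(out, "mean_depth") <- mean_depth
  out
}

#' Inject genotype missingness
#'
#' Entries are set to missing independently: every entry of a targeted SNP
#' column with probability `snp_rate`, and every entry of a targeted sample
#' row with probability `sample_rate` (an entry hit by either mask becomes
#' missing).
#'
#' @param gm a [genotype_matrix()].
#' @param snp_rate,sample_rate missingness probabilities in `[0, 1)`.
#' @param snps,samples indices or names restricting which columns/rows are
#'   targeted (default: all).
#' @param seed optional integer seed.
#' @return the modified `genotype_matrix`.
#' @export
inject_missingness <- function(gm, snp_rate = 0, sample_rate = 0,
                               snps = NULL, samples = NULL, seed = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (snp_rate < 0 || snp_rate >= 1 || sample_rate < 0 || sample_rate >= 1)
    stop("rates must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  g <- gm$genotypes
  n <- nrow(g); m <- ncol(g)
  vi <- snps %||% seq_len(m)
  if (is.character(vi)) vi <- match(vi, colnames(g))
  si <- samples %||% seq_len(n)
  if (is.character(si)) si <- match(si, rownames(g))
  if (snp_rate > 0 && length(vi))
    for (j in vi) g[stats::runif(n) < snp_rate, j] <- NA
  if (sample_rate > 0 && length(si))
    for (i in si) g[i, stats::runif(m) < sample_rate] <- NA
  gm$genotypes <- g
  gm
}
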