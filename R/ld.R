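#' Pairwise linkage-disequilibrium statistics for two SNPs
#'
#' Two-locus haplotype frequencies are estimated by EM from unphased
#' genotypes (only the double heterozygote is phase-ambiguous), then
#' `D = p11 - pA * pB`, `D' = |D| / Dmax` and
#' `r2 = D^2 / (pA (1-pA) pB (1-pB))`. A confidence interval for `|D'|`
#' comes from a likelihood profile over an evenly spaced grid (default 21
#' points on `[0, 1]`): grid likelihoods are normalized and the 5% / 95%
#' cumulative bounds reported, the standard construction behind
#' confidence-interval haplotype blocks.
#'
#' If the genotype input contains no heterozygotes (e.g. phased haplotypes
#' encoded as homozygous diploids, dosage `2 * h`), the EM solution equals
#' the observed joint frequencies exactly and `r2` equals the squared
#' Pearson correlation of the allele indicators.
#'
#' @param gm a [genotype_matrix()] or plain dosage matrix.
#' @param snp_i,snp_j column indices or SNP names.
#' @param grid_points number of D' grid points for the CI profile.
#' @param ci_alpha tail mass for each CI bound (default 5%).
#' @param ci compute the D' confidence interval (default); `FALSE` skips
#'   the likelihood profile when only D/D'/r2 are needed.
#' @return one-row data frame of class `ld_pair`: `snp_i`, `snp_j`, `D`,
#'   `D_prime`, `r2`, `ci_low`, `ci_high`, `undefined` (monomorphic flag).
#' @export
ld_stats <- function(gm, snp_i, snp_j, grid_points = 21, ci_alpha = 0.05,
                     ci = TRUE) {
  g <- if (inherits(gm, "genotype_matrix")) gm$genotypes else as.matrix(gm)
  if (is.character(snp_i)) snp_i <- match(snp_i, colnames(g))
  if (is.character(snp_j)) snp_j <- match(snp_j, colnames(g))
  gi <- g[, snp_i]; gj <- g[, snp_j]
  cc <- !is.na(gi) & !is.na(gj)
  gi <- gi[cc]; gj <- gj[cc]
  name_i <- colnames(g)[snp_i] %||% as.character(snp_i)
  name_j <- colnames(g)[snp_j] %||% as.character(snp_j)
  out <- data.frame(snp_i = name_i, snp_j = name_j, D = NA_real_,
                    D_prime = NA_real_, r2 = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, undefined = TRUE,
                    stringsAsFactors = FALSE)
  class(out) <- c("ld_pair", "data.frame")
  if (length(gi) == 0 || stats::var(gi) == 0 || stats::var(gj) == 0)
    return(out)

  tab <- table(factor(gi, 0:2), factor(gj, 0:2))
  f <- two_locus_em(tab)
  pA <- f["p11"] + f["p10"]; pB <- f["p11"] + f["p01"]
  D <- unname(f["p11"] - pA * pB)
  Dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  dprime <- if (Dmax > 0) abs(D) / Dmax else 0
  r2 <- unname(D^2 / (pA * (1 - pA) * pB * (1 - pB)))

  out$D <- D; out$D_prime <- dprime; out$r2 <- r2
  out$undefined <- FALSE
  if (!ci) return(out)

  # likelihood profile for |D'| at fixed allele frequencies
  grid <- seq(0, 1, length.out = grid_points)
  sgn <- if (D >= 0) 1 else -1
  ll <- vapply(grid, function(dp) {
    Dg <- sgn * dp * Dmax
    p11 <- max(pA * pB + Dg, 1e-12)
    p10 <- max(pA - p11, 1e-12)
    p01 <- max(pB - p11, 1e-12)
    p00 <- max(1 - p11 - p10 - p01, 1e-12)
    gp <- matrix(c(p00^2, 2 * p00 * p01, p01^2,
                   2 * p00 * p10, 2 * p11 * p00 + 2 * p10 * p01, 2 * p01 * p11,
                   p10^2, 2 * p10 * p11, p11^2), 3, 3, byrow = TRUE)
    sum(tab * log(gp))
  }, numeric(1))
  w <- exp(ll - max(ll)); w <- w / sum(w)
  cw <- cumsum(w)
  ci_low <- grid[which(cw >= ci_alpha)[1]]
  ci_high <- grid[which(cw >= 1 - ci_alpha)[1]]

  out$ci_low <- ci_low; out$ci_high <- ci_high
  out
}

#' All-pairs LD statistics for a SNP panel
#'
#' @param gm a [genotype_matrix()] or dosage matrix.
#' @param snps column indices or names (default: all, in column order).
#' @param ... passed to [ld_stats()].
#' @return data frame with one [ld_stats()] row per pair `i < j`, plus
#'   integer index columns `i`, `j` in panel order.
#' @export
ld_matrix <- function(gm, snps = NULL, ...) {
  g <- if (inherits(gm, "genotype_matrix")) gm$genotypes else as.matrix(gm)
  snps <- snps %||% seq_len(ncol(g))
  if (is.character(snps)) snps <- match(snps, colnames(g))
  k <- length(snps)
  rows <- list()
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      r <- ld_stats(g, snps[a], snps[b], ...)
      r$i <- a; r$j <- b
      rows[[length(rows) + 1]] <- r
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
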