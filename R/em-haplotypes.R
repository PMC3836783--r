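#' EM haplotype-frequency estimation for unphased genotypes
#'
#' Maximum-likelihood haplotype frequencies at k SNPs from unphased
#' multilocus genotypes. Individuals are grouped into genotype ambiguity
#' classes; each class enumerates its compatible (unordered) haplotype
#' pairs once, and the EM expectation step weights pairs by current
#' frequencies. Initialization is the product of single-SNP allele
#' frequencies (linkage equilibrium); for degenerate inputs consisting only
#' of double heterozygotes this start is the uniform fixed point, which is
#' the documented convention. The log-likelihood is non-decreasing across
#' iterations and its trace is returned as an attribute.
#'
#' Rows containing missing genotypes are dropped (with a message) before
#' estimation.
#'
#' @param geno matrix of dosages (individuals x k SNPs), k between 2 and
#'   `max_snps`.
#' @param tol convergence tolerance on the maximum frequency change.
#' @param max_iter iteration cap; non-convergence yields a warning and the
#'   best estimate.
#' @param max_snps guard on k (pair enumeration is exponential in the
#'   number of heterozygous sites).
#' @return named numeric vector of haplotype frequencies (names are 0/1
#'   strings in SNP order, e.g. `"01"`), summing to 1; attributes
#'   `loglik` (trace) and `converged`.
#' @export
em_haplotype_freqs <- function(geno, tol = 1e-8, max_iter = 1000,
                               max_snps = 8) {
  geno <- as.matrix(geno)
  k <- ncol(geno)
  if (k < 2) stop("need at least 2 SNPs")
  if (k > max_snps) stop("k exceeds max_snps (", max_snps, ")")
  cc <- stats::complete.cases(geno)
  if (!all(cc)) {
    message(sprintf("dropping %d individual(s) with missing genotypes", sum(!cc)))
    geno <- geno[cc, , drop = FALSE]
  }
  n <- nrow(geno)
  if (n == 0) stop("no complete-case individuals")

  key <- apply(geno, 1, paste, collapse = "")
  classes <- unique(key)
  class_n <- as.numeric(table(key)[classes])
  class_geno <- geno[match(classes, key), , drop = FALSE]

  hap_code <- function(bits) sum(bits * 2^(seq_len(k) - 1)) + 1L
  pairs_of <- function(g) {
    het <- which(g == 1L)
    base <- as.integer(g == 2L)
    if (length(het) == 0) {
      h <- hap_code(base)
      return(matrix(c(h, h), 1))
    }
    free <- het[-1]
    n_cfg <- 2^length(free)
    out <- matrix(0L, n_cfg, 2)
    for (cfg in seq_len(n_cfg) - 1L) {
      b1 <- base; b2 <- base
      b1[het[1]] <- 1L; b2[het[1]] <- 0L
      if (length(free)) {
        bits <- as.integer(intToBits(cfg))[seq_along(free)]
        b1[free] <- bits; b2[free] <- 1L - bits
      }
      out[cfg + 1L, ] <- c(hap_code(b1), hap_code(b2))
    }
    out
  }
  pair_list <- lapply(seq_len(nrow(class_geno)),
                      function(i) pairs_of(class_geno[i, ]))

  involved <- sort(unique(unlist(pair_list)))
  idx <- integer(2^k); idx[involved] <- seq_along(involved)
  pair_list <- lapply(pair_list, function(p)
    matrix(idx[p], ncol = 2))
  H <- length(involved)
  hap_bits <- t(vapply(involved - 1L, function(code)
    as.integer(intToBits(code))[seq_len(k)], integer(k)))
  hap_names <- apply(hap_bits, 1, paste, collapse = "")

  p_allele <- colMeans(geno) / 2
  f <- apply(hap_bits, 1, function(b)
    prod(ifelse(b == 1, p_allele, 1 - p_allele)))
  f <- f / sum(f)

  loglik <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    counts <- numeric(H)
    ll <- 0
    for (ci in seq_along(pair_list)) {
      p <- pair_list[[ci]]
      w <- f[p[, 1]] * f[p[, 2]] * ifelse(p[, 1] != p[, 2], 2, 1)
      s <- sum(w)
      if (s <= 0) { w <- rep(1 / nrow(p), nrow(p)); s <- 1e-300 }
      else w <- w / s
      ll <- ll + class_n[ci] * log(s)
      inc <- class_n[ci] * w
      for (r in seq_len(nrow(p))) {
        counts[p[r, 1]] <- counts[p[r, 1]] + inc[r]
        counts[p[r, 2]] <- counts[p[r, 2]] + inc[r]
      }
    }
    loglik <- c(loglik, ll)
    f_new <- counts / (2 * n)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM did not converge within ", max_iter, " iterations")
  names(f) <- hap_names
  attr(f, "loglik") <- loglik
  attr(f, "converged") <- converged
  f
}

# Fast specialised two-locus EM on the 3x3 genotype count table.
# Returns c(p00, p01, p10, p11) where the second index is the second SNP
# and "1" is the counted allele. Only the double heterozygote is phase
# ambiguous; its coupling probability is re-estimated each iteration.
two_locus_em <- function(tab, tol = 1e-10, max_iter = 1000) {
  stopifnot(all(dim(tab) == c(3, 3)))
  n <- sum(tab)
  if (n == 0) stop("empty genotype table")
  # deterministic haplotype contributions (counts of 2n haplotypes)
  base11 <- 2 * tab[3, 3] + tab[3, 2] + tab[2, 3]
  base10 <- 2 * tab[3, 1] + tab[3, 2] + tab[2, 1]
  base01 <- 2 * tab[1, 3] + tab[1, 2] + tab[2, 3]
  base00 <- 2 * tab[1, 1] + tab[1, 2] + tab[2, 1]
  dh <- tab[2, 2]
  pA <- (2 * (tab[3, 1] + tab[3, 2] + tab[3, 3]) +
           tab[2, 1] + tab[2, 2] + tab[2, 3]) / (2 * n)
  pB <- (2 * (tab[1, 3] + tab[2, 3] + tab[3, 3]) +
           tab[1, 2] + tab[2, 2] + tab[3, 2]) / (2 * n)
  f <- c(p00 = (1 - pA) * (1 - pB), p01 = (1 - pA) * pB,
         p10 = pA * (1 - pB), p11 = pA * pB)
  for (it in seq_len(max_iter)) {
    cis <- f["p11"] * f["p00"]
    tra <- f["p10"] * f["p01"]
    q <- if (cis + tra > 0) cis / (cis + tra) else 0.5
    c11 <- base11 + dh * q
    c00 <- base00 + dh * q
    c10 <- base10 + dh * (1 - q)
    c01 <- base01 + dh * (1 - q)
    f_new <- c(c00, c01, c10, c11) / (2 * n)
    names(f_new) <- names(f)
    if (max(abs(f_new - f)) < tol) { f <- f_new; break }
    f <- f_new
  }
  f
}
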