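#' Confidence-interval haplotype blocks
#'
#' Gabriel-style block construction from pairwise D' confidence intervals:
#' a pair is in "strong LD" when `ci_low >= strong_ci_low` and
#' `ci_high >= strong_ci_high`; it shows "strong evidence of historical
#' recombination" when `ci_high < recomb_ci_high`; other pairs are
#' uninformative. A span `[i, j]` is a candidate block when its outermost
#' pair is strong and at least `min_strong_frac` of its informative pairs
#' are strong. Candidates are accepted greedily from longest to shortest,
#' skipping overlaps, so returned blocks are disjoint and ordered.
#'
#' An optional pre-pass drops SNPs whose maximum r-squared with every other
#' panel SNP is below `r2_floor`, mirroring the ad-hoc practice of
#' excluding weakly correlated SNPs before re-blocking (off by default).
#'
#' @param ld_pairs all-pairs data frame from [ld_matrix()] (columns `i`,
#'   `j`, `ci_low`, `ci_high`, `r2`) for SNPs ordered by position.
#' @param n_snps number of SNPs in the panel.
#' @param positions optional bp positions used to verify ordering.
#' @param strong_ci_low,strong_ci_high,recomb_ci_high CI thresholds.
#' @param min_strong_frac minimum fraction of informative pairs in strong
#'   LD within an accepted block.
#' @param r2_floor optional r-squared exclusion floor (default `NULL`, no
#'   pre-pass).
#' @return list of blocks, each a list with `start`, `end` (panel indices)
#'   and `snps` (indices covered); empty list when no block qualifies.
#' @export
build_blocks <- function(ld_pairs, n_snps, positions = NULL,
                         strong_ci_low = 0.70, strong_ci_high = 0.98,
                         recomb_ci_high = 0.90, min_strong_frac = 0.95,
                         r2_floor = NULL) {
  if (!is.null(positions) && is.unsorted(positions, strictly = TRUE))
    stop("SNPs must be ordered by strictly increasing position")
  keep <- seq_len(n_snps)
  if (!is.null(r2_floor)) {
    max_r2 <- vapply(keep, function(s)
      suppressWarnings(max(ld_pairs$r2[ld_pairs$i == s | ld_pairs$j == s],
                           na.rm = TRUE)), numeric(1))
    keep <- keep[is.finite(max_r2) & max_r2 >= r2_floor]
    if (length(keep) < 2) return(list())
    ld_pairs <- ld_pairs[ld_pairs$i %in% keep & ld_pairs$j %in% keep, ]
    ld_pairs$i <- match(ld_pairs$i, keep)
    ld_pairs$j <- match(ld_pairs$j, keep)
  }
  k <- length(keep)
  strong <- matrix(FALSE, k, k); inform <- matrix(FALSE, k, k)
  for (r in seq_len(nrow(ld_pairs))) {
    i <- ld_pairs$i[r]; j <- ld_pairs$j[r]
    if (is.na(ld_pairs$ci_low[r])) next
    s <- ld_pairs$ci_low[r] >= strong_ci_low &&
      ld_pairs$ci_high[r] >= strong_ci_high
    rec <- ld_pairs$ci_high[r] < recomb_ci_high
    strong[i, j] <- s
    inform[i, j] <- s || rec
  }
  cand <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (!strong[i, j]) next
      ii <- i:j
      sub_s <- strong[ii, ii]; sub_i <- inform[ii, ii]
      ns <- sum(sub_s[upper.tri(sub_s)])
      ni <- sum(sub_i[upper.tri(sub_i)])
      if (ni == 0) next
      if (ns / ni >= min_strong_frac)
        cand[[length(cand) + 1]] <- c(i, j)
    }
  }
  if (!length(cand)) return(list())
  cand <- cand[order(-vapply(cand, function(x) x[2] - x[1], numeric(1)),
                     vapply(cand, `[`, numeric(1), 1))]
  used <- rep(FALSE, k)
  blocks <- list()
  for (b in cand) {
    if (any(used[b[1]:b[2]])) next
    used[b[1]:b[2]] <- TRUE
    blocks[[length(blocks) + 1]] <-
      list(start = keep[b[1]], end = keep[b[2]], snps = keep[b[1]:b[2]])
  }
  blocks[order(vapply(blocks, `[[`, numeric(1), "start"))]
}

#' Haplotype association within a block
#'
#' Haplotype frequencies are estimated by EM separately in cases and
#' controls; haplotypes with pooled frequency below `min_hap_freq` are
#' collapsed into a `"rare"` class. Each haplotype is tested against all
#' others with a Pearson chi-square (1 df) on the 2x2 table of EM-expected
#' haplotype counts by status. The block P-value is the minimum over
#' tested haplotypes.
#'
#' @param gm a [genotype_matrix()] with phenotype labels.
#' @param snps block SNP indices or names.
#' @param min_hap_freq pooling threshold for rare haplotypes.
#' @return list with `table` (haplotype, freq_cases, freq_controls, chi2,
#'   p, rare flag) and `block_p`.
#' @export
haplotype_association <- function(gm, snps, min_hap_freq = 0.01) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(gm$phenotype)) stop("phenotype labels required")
  if (is.character(snps)) snps <- match(snps, colnames(gm$genotypes))
  g <- gm$genotypes[, snps, drop = FALSE]
  ca <- g[gm$phenotype == 1, , drop = FALSE]
  co <- g[gm$phenotype == 0, , drop = FALSE]
  if (ncol(g) == 1) {
    # single-SNP block reduces to the allelic test on that SNP
    res <- allelic_chisq(ca[, 1], co[, 1])
    tab <- data.frame(haplotype = c("1", "0"),
                      freq_cases = c(res$maf_cases, 1 - res$maf_cases),
                      freq_controls = c(res$maf_controls, 1 - res$maf_controls),
                      chi2 = res$chi2, p = res$p, rare = FALSE,
                      stringsAsFactors = FALSE)
    return(list(table = tab, block_p = res$p))
  }
  f_ca <- em_haplotype_freqs(ca, max_snps = ncol(g))
  f_co <- em_haplotype_freqs(co, max_snps = ncol(g))
  haps <- union(names(f_ca), names(f_co))
  get <- function(f, h) ifelse(h %in% names(f), unname(f[h]), 0)
  n2_ca <- 2 * sum(stats::complete.cases(ca))
  n2_co <- 2 * sum(stats::complete.cases(co))
  fc <- vapply(haps, function(h) get(f_ca, h), numeric(1))
  fo <- vapply(haps, function(h) get(f_co, h), numeric(1))
  pooled <- (n2_ca * fc + n2_co * fo) / (n2_ca + n2_co)
  rare <- pooled < min_hap_freq
  if (any(rare)) {
    fc <- c(fc[!rare], rare = sum(fc[rare]))
    fo <- c(fo[!rare], rare = sum(fo[rare]))
    haps <- c(haps[!rare], "rare")
    rare <- c(rep(FALSE, sum(!rare)), TRUE)
  }
  test <- function(ec, eo) {
    tab <- rbind(c(ec, n2_ca - ec), c(eo, n2_co - eo))
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(E == 0)) return(c(0, 1))
    chi2 <- sum((tab - E)^2 / E)
    c(chi2, stats::pchisq(chi2, 1, lower.tail = FALSE))
  }
  stats_m <- t(vapply(seq_along(haps), function(i)
    test(n2_ca * fc[i], n2_co * fo[i]), numeric(2)))
  tab <- data.frame(haplotype = haps, freq_cases = unname(fc),
                    freq_controls = unname(fo), chi2 = stats_m[, 1],
                    p = stats_m[, 2], rare = rare, stringsAsFactors = FALSE)
  list(table = tab, block_p = min(tab$p))
}
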