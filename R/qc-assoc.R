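#' Quality-control configuration
#'
#' Default thresholds follow the standard candidate-gene association
#' toolchain: samples with more than 25% missing genotypes, SNPs with more
#' than 10% missing genotypes, SNPs with minor allele frequency below 1%
#' and SNPs departing from Hardy-Weinberg equilibrium at P below 1e-5 are
#' excluded; 5e-8 marks genome-wide significance.
#'
#' @param max_sample_missing,max_snp_missing missing-fraction thresholds.
#' @param min_maf minimum minor allele frequency.
#' @param min_hwe_p minimum Hardy-Weinberg exact P.
#' @param gw_sig genome-wide significance level.
#' @param hwe_controls_only compute the HWE test in controls only
#'   (default); `FALSE` uses the full cohort.
#' @return an object of class `qc_config`.
#' @export
qc_config <- function(max_sample_missing = 0.25, max_snp_missing = 0.10,
                      min_maf = 0.01, min_hwe_p = 1e-5, gw_sig = 5e-8,
                      hwe_controls_only = TRUE) {
  vals <- c(max_sample_missing, max_snp_missing, min_maf, min_hwe_p, gw_sig)
  if (any(vals <= 0 | vals >= 1)) stop("all thresholds must lie in (0, 1)")
  structure(list(max_sample_missing = max_sample_missing,
                 max_snp_missing = max_snp_missing, min_maf = min_maf,
                 min_hwe_p = min_hwe_p, gw_sig = gw_sig,
                 hwe_controls_only = hwe_controls_only),
            class = "qc_config")
}

#' Apply cohort quality-control filters
#'
#' Filters in order, recomputing after each step: (1) samples with missing
#' fraction above `max_sample_missing`; (2) SNPs with missing fraction
#' above `max_snp_missing`; (3) SNPs with minor allele frequency below
#' `min_maf`; (4) SNPs with Hardy-Weinberg exact P (in controls, by
#' default) below `min_hwe_p`. Every exclusion is listed with its reason.
#'
#' @param gm a [genotype_matrix()] with phenotype labels.
#' @param config a [qc_config()].
#' @return list with `genotypes` (the filtered `genotype_matrix`, possibly
#'   with zero rows/columns) and `report` (data frame of exclusions:
#'   `step`, `type`, `id`, `value`, `reason`).
#' @export
qc_filter <- function(gm, config = qc_config()) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(config, "qc_config"))
  if (is.null(gm$phenotype)) stop("qc_filter requires phenotype labels")
  rep_rows <- list()
  note <- function(step, type, id, value, reason)
    rep_rows[[length(rep_rows) + 1]] <<- data.frame(
      step = step, type = type, id = id, value = value, reason = reason,
      stringsAsFactors = FALSE)

  g <- gm$genotypes; phe <- gm$phenotype
  # 1. sample missingness
  fr <- rowMeans(is.na(g))
  drop <- fr > config$max_sample_missing
  for (i in which(drop))
    note(1L, "sample", rownames(g)[i], fr[i],
         sprintf("missing fraction > %g", config$max_sample_missing))
  g <- g[!drop, , drop = FALSE]; phe <- phe[!drop]

  # 2. SNP missingness (recomputed on surviving samples)
  if (nrow(g) > 0) {
    fr <- colMeans(is.na(g))
    drop <- fr > config$max_snp_missing
    for (j in which(drop))
      note(2L, "snp", colnames(g)[j], fr[j],
           sprintf("missing fraction > %g", config$max_snp_missing))
    g <- g[, !drop, drop = FALSE]
  }

  # 3. minor allele frequency
  if (nrow(g) > 0 && ncol(g) > 0) {
    mafs <- apply(g, 2, maf)
    drop <- is.na(mafs) | mafs < config$min_maf
    for (j in which(drop))
      note(3L, "snp", colnames(g)[j], mafs[j],
           sprintf("maf < %g", config$min_maf))
    g <- g[, !drop, drop = FALSE]
  }

  # 4. Hardy-Weinberg in controls (or full cohort)
  if (nrow(g) > 0 && ncol(g) > 0) {
    rows <- if (config$hwe_controls_only) which(phe == 0) else seq_along(phe)
    hp <- apply(g[rows, , drop = FALSE], 2, function(col) {
      tab <- tabulate(col + 1L, nbins = 3L)
      if (sum(tab) == 0) return(1)
      hwe_exact_test(tab[1], tab[2], tab[3])
    })
    drop <- hp < config$min_hwe_p
    for (j in which(drop))
      note(4L, "snp", colnames(g)[j], hp[j],
           sprintf("HWE P < %g", config$min_hwe_p))
    g <- g[, !drop, drop = FALSE]
  }

  keep_snps <- match(colnames(g), gm$map$snp)
  out <- structure(list(
    genotypes = g, phenotype = phe,
    map = gm$map[keep_snps, , drop = FALSE]), class = "genotype_matrix")
  report <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(step = integer(), type = character(), id = character(),
               value = numeric(), reason = character(),
               stringsAsFactors = FALSE)
  list(genotypes = out, report = report)
}

#' Allelic chi-square association test for one SNP
#'
#' Pearson chi-square (1 df, no continuity correction) on the 2x2
#' allele-count-by-status table, with the odds ratio as the cross-product
#' ratio of the counted (minor) allele; 0.5 is added to every cell only if
#' some cell is zero. Missing genotypes are excluded pairwise.
#'
#' @param case_g,control_g dosage vectors (0/1/2, `NA` allowed) for cases
#'   and controls; each group needs at least one non-missing genotype.
#' @return one-row data frame: `chi2`, `p`, `odds_ratio`, `maf_cases`,
#'   `maf_controls`, `n_cases`, `n_controls`, `monomorphic`.
#' @export
allelic_chisq <- function(case_g, control_g) {
  n_ca <- sum(!is.na(case_g)); n_co <- sum(!is.na(control_g))
  if (n_ca < 1 || n_co < 1) stop("each group needs >= 1 non-missing genotype")
  a <- sum(case_g, na.rm = TRUE); b <- 2 * n_ca - a      # cases: minor, major
  c_ <- sum(control_g, na.rm = TRUE); d <- 2 * n_co - c_ # controls
  maf_ca <- a / (2 * n_ca); maf_co <- c_ / (2 * n_co)
  if ((a + c_) == 0 || (b + d) == 0) {
    return(data.frame(chi2 = 0, p = 1, odds_ratio = NA_real_,
                      maf_cases = maf_ca, maf_controls = maf_co,
                      n_cases = n_ca, n_controls = n_co, monomorphic = TRUE))
  }
  N <- a + b + c_ + d
  chi2 <- N * (a * d - b * c_)^2 /
    ((a + b) * (c_ + d) * (a + c_) * (b + d))
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  if (any(c(a, b, c_, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * c_)
  data.frame(chi2 = chi2, p = p, odds_ratio = or,
             maf_cases = maf_ca, maf_controls = maf_co,
             n_cases = n_ca, n_controls = n_co, monomorphic = FALSE)
}

#' Single-SNP allelic association scan
#'
#' Runs [allelic_chisq()] for every SNP of a case-control cohort and flags
#' genome-wide significant hits.
#'
#' @param gm a [genotype_matrix()] with phenotype labels (normally after
#'   [qc_filter()]).
#' @param config a [qc_config()] (supplies the significance level).
#' @return data frame, one row per SNP, with SNP metadata, test results
#'   and `gw_significant`.
#' @export
assoc_scan <- function(gm, config = qc_config()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(gm$phenotype)) stop("assoc_scan requires phenotype labels")
  ca <- gm$phenotype == 1; co <- gm$phenotype == 0
  rows <- lapply(seq_len(ncol(gm$genotypes)), function(j)
    allelic_chisq(gm$genotypes[ca, j], gm$genotypes[co, j]))
  res <- do.call(rbind, rows)
  out <- cbind(gm$map[, c("snp", "chrom", "pos", "a1", "a2")], res)
  out$gw_significant <- !is.na(out$p) & out$p < config$gw_sig
  rownames(out) <- NULL
  out
}

#' Genotyping-rate report
#'
#' Call rates (fractions of non-missing entries) per SNP, per sample and
#' overall.
#'
#' @param gm a [genotype_matrix()].
#' @return list with `per_snp`, `per_sample` and `overall` rates.
#' @export
genotyping_rate_report <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  g <- gm$genotypes
  list(per_snp = colMeans(!is.na(g)),
       per_sample = rowMeans(!is.na(g)),
       overall = mean(!is.na(g)))
}
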