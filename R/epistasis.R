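#' Pairwise SNP-by-SNP epistasis test
#'
#' Default (`method = "logistic"`): the full logistic interaction model
#' `status ~ g_a + g_b + g_a:g_b` on allele dosages, fitted by iteratively
#' reweighted least squares on genotype-aggregated binomial counts (up to
#' nine cells), with a Wald test on the interaction coefficient. The
#' aggregated fit is identical to the per-individual fit.
#'
#' `method = "fast"` uses the allele-count approximation: a composite 2x2
#' two-locus allele table is built per status group from dosage
#' cross-products (double heterozygotes split evenly, phase ignored), and
#' the statistic is the difference of the two log odds ratios divided by
#' its standard error (sum of inverse cell counts). It is an approximation
#' that trades the genotype model for speed.
#'
#' Separation or non-convergence is flagged `estimable = FALSE` rather
#' than raising an error, so scans can skip such pairs.
#'
#' @param gm a [genotype_matrix()] with phenotype labels.
#' @param snp_a,snp_b SNP indices or names.
#' @param method `"logistic"` (default) or `"fast"`.
#' @param min_samples minimum complete-case sample count.
#' @return one-row data frame: `snp_a`, `snp_b`, `beta_int`, `se_int`,
#'   `z`, `p`, `n_used`, `estimable`, `method`.
#' @export
pairwise_epistasis <- function(gm, snp_a, snp_b,
                               method = c("logistic", "fast"),
                               min_samples = 50) {
  method <- match.arg(method)
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(gm$phenotype)) stop("phenotype labels required")
  g <- gm$genotypes
  if (is.character(snp_a)) snp_a <- match(snp_a, colnames(g))
  if (is.character(snp_b)) snp_b <- match(snp_b, colnames(g))
  ga <- g[, snp_a]; gb <- g[, snp_b]; y <- gm$phenotype
  cc <- !is.na(ga) & !is.na(gb) & !is.na(y)
  ga <- ga[cc]; gb <- gb[cc]; y <- y[cc]
  n_used <- length(y)
  if (n_used < min_samples)
    stop("fewer than ", min_samples, " complete-case samples")
  name_a <- colnames(g)[snp_a] %||% as.character(snp_a)
  name_b <- colnames(g)[snp_b] %||% as.character(snp_b)
  bail <- function() data.frame(
    snp_a = name_a, snp_b = name_b, beta_int = NA_real_, se_int = NA_real_,
    z = NA_real_, p = NA_real_, n_used = n_used, estimable = FALSE,
    method = method, stringsAsFactors = FALSE)
  if (stats::var(ga) == 0 || stats::var(gb) == 0) return(bail())

  if (method == "logistic") {
    key <- interaction(ga, gb, drop = TRUE)
    agg <- data.frame(
      ga = as.numeric(tapply(ga, key, `[`, 1)),
      gb = as.numeric(tapply(gb, key, `[`, 1)),
      n_case = as.numeric(tapply(y, key, sum)),
      n_tot = as.numeric(tapply(y, key, length)))
    agg$n_ctrl <- agg$n_tot - agg$n_case
    fit <- suppressWarnings(stats::glm(
      cbind(n_case, n_ctrl) ~ ga * gb, family = stats::binomial(),
      data = agg, control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
    co <- summary(fit)$coefficients
    if (!fit$converged || !("ga:gb" %in% rownames(co))) return(bail())
    beta <- co["ga:gb", "Estimate"]; se <- co["ga:gb", "Std. Error"]
    if (!is.finite(beta) || !is.finite(se) || abs(beta) > 15 || se > 50)
      return(bail())
  } else {
    comp_tab <- function(a, b) {
      t11 <- sum(a * b) / 2
      t10 <- sum(a * (2 - b)) / 2
      t01 <- sum((2 - a) * b) / 2
      t00 <- sum((2 - a) * (2 - b)) / 2
      m <- c(t11, t10, t01, t00)
      if (any(m == 0)) m <- m + 0.5
      m
    }
    ta <- comp_tab(ga[y == 1], gb[y == 1])
    tu <- comp_tab(ga[y == 0], gb[y == 0])
    lor <- function(t) log(t[1] * t[4] / (t[2] * t[3]))
    beta <- lor(ta) - lor(tu)
    se <- sqrt(sum(1 / ta) + sum(1 / tu))
    if (!is.finite(beta) || !is.finite(se)) return(bail())
  }
  z <- beta / se
  data.frame(snp_a = name_a, snp_b = name_b, beta_int = beta, se_int = se,
             z = z, p = 2 * stats::pnorm(-abs(z)), n_used = n_used,
             estimable = TRUE, method = method, stringsAsFactors = FALSE)
}

#' Scan all focal-by-partner SNP pairs for epistasis
#'
#' Tests every pair of one focal gene's SNPs against a partner SNP set
#' (e.g. SNPs of functionally grouped interacting genes) and summarizes
#' the scan: planned test count, Bonferroni threshold and minimum-P pair.
#'
#' @param gm a [genotype_matrix()] with phenotype labels.
#' @param focal_snps,partner_snps SNP name vectors (partner may be empty).
#' @param partner_gene_map optional data frame with `snp` and `gene`
#'   columns giving partner-gene membership (counted in the summary).
#' @param method passed to [pairwise_epistasis()].
#' @param alpha family-wise level for the Bonferroni threshold.
#' @param plan_only if `TRUE`, return the scan summary without fitting
#'   (useful to size large scans before committing).
#' @return list with `results` (data frame sorted by P) and `summary`
#'   (list: `n_focal`, `n_partner_snps`, `n_partner_genes`, `n_tests`,
#'   `bonferroni`, `top`).
#' @export
gene_group_scan <- function(gm, focal_snps, partner_snps,
                            partner_gene_map = NULL, method = "logistic",
                            alpha = 0.05, plan_only = FALSE) {
  if (length(focal_snps) == 0) stop("focal_snps must be non-empty")
  n_tests <- length(focal_snps) * length(partner_snps)
  n_genes <- if (!is.null(partner_gene_map))
    length(unique(partner_gene_map$gene[partner_gene_map$snp %in% partner_snps]))
  else NA_integer_
  summ <- list(n_focal = length(focal_snps),
               n_partner_snps = length(partner_snps),
               n_partner_genes = n_genes, n_tests = n_tests,
               bonferroni = if (n_tests > 0) alpha / n_tests else NA_real_,
               top = NULL)
  empty <- data.frame(snp_a = character(), snp_b = character(),
                      beta_int = numeric(), se_int = numeric(),
                      z = numeric(), p = numeric(), n_used = integer(),
                      estimable = logical(), method = character(),
                      stringsAsFactors = FALSE)
  if (plan_only || n_tests == 0)
    return(list(results = empty, summary = summ))
  rows <- list()
  for (a in focal_snps) for (b in partner_snps)
    rows[[length(rows) + 1]] <- pairwise_epistasis(gm, a, b, method = method)
  res <- do.call(rbind, rows)
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  est <- res[res$estimable, , drop = FALSE]
  if (nrow(est)) summ$top <- est[1, ]
  list(results = res, summary = summ)
}
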