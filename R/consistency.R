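#' Per-SNP logistic Wald Z-scores
#'
#' For each SNP, the univariate logistic regression
#' `status ~ intercept + dosage` is fitted and the Wald Z-score (slope
#' divided by its standard error) reported. Because the covariate takes at
#' most three values, individuals are aggregated into genotype cells and
#' the binomial fit runs on at most three rows via `stats::glm.fit`
#' (identical estimates and standard errors to the per-individual fit);
#' the covariance is the inverse Fisher information at convergence.
#' Monomorphic SNPs and separated fits are flagged not estimable.
#'
#' @param gm a [genotype_matrix()] with phenotype labels.
#' @param snps SNP indices or names (default all).
#' @return data frame: `snp`, `beta`, `se`, `z`, `estimable`.
#' @export
per_snp_logistic_z <- function(gm, snps = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(gm$phenotype)) stop("phenotype labels required")
  g <- gm$genotypes
  snps <- snps %||% seq_len(ncol(g))
  if (is.character(snps)) snps <- match(snps, colnames(g))
  y <- gm$phenotype
  fam <- stats::binomial()
  one <- function(j) {
    gj <- g[, j]
    cc <- !is.na(gj) & !is.na(y)
    gj <- gj[cc]; yj <- y[cc]
    bail <- data.frame(snp = colnames(g)[j], beta = NA_real_, se = NA_real_,
                       z = NA_real_, estimable = FALSE,
                       stringsAsFactors = FALSE)
    if (length(gj) == 0 || stats::var(gj) == 0) return(bail)
    lev <- sort(unique(gj))
    n_case <- vapply(lev, function(l) sum(yj[gj == l]), numeric(1))
    n_tot <- vapply(lev, function(l) sum(gj == l), numeric(1))
    X <- cbind(1, lev)
    fit <- suppressWarnings(stats::glm.fit(
      X, n_case / n_tot, weights = n_tot, family = fam,
      control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
    mu <- fit$fitted.values
    W <- n_tot * mu * (1 - mu)
    info <- crossprod(X, W * X)
    vc <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(vc) || !fit$converged) return(bail)
    beta <- fit$coefficients[2]; se <- sqrt(vc[2, 2])
    if (!is.finite(beta) || !is.finite(se) || abs(beta) > 15 || se > 100)
      return(bail)
    data.frame(snp = colnames(g)[j], beta = unname(beta), se = se,
               z = unname(beta / se), estimable = TRUE,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(snps, one))
  rownames(out) <- NULL
  out
}

#' Causal-variant consistency fit: |Z| on sqrt(r2)
#'
#' Ordinary least squares of absolute per-SNP Z-scores on the square root
#' of r-squared with a designated candidate SNP. If the candidate (or a
#' perfect proxy) is causal, SNPs in high LD with it mirror its Z-score
#' and the slope approaches the candidate's own |Z|; with no association
#' the slope approaches 0. The candidate's own point (r = 1) is excluded
#' by default to avoid self-regression.
#'
#' @param z named vector of per-SNP Z-scores (sign is ignored; `NA`
#'   entries are dropped).
#' @param r2 vector of r-squared values with the candidate, aligned with
#'   `z` (same order/names).
#' @param candidate optional SNP name identifying the candidate's own
#'   entry.
#' @param include_candidate keep the candidate's own point (default
#'   `FALSE`).
#' @return an object of class `consistency_fit`: list with `candidate`,
#'   `n_snps`, `slope`, `intercept`, `slope_se`, `intercept_se`, `points`
#'   (data frame `snp`, `sqrt_r2`, `abs_z`).
#' @export
consistency_fit <- function(z, r2, candidate = NULL,
                            include_candidate = FALSE) {
  if (length(z) != length(r2)) stop("z and r2 must be aligned")
  snp <- names(z) %||% as.character(seq_along(z))
  keep <- !is.na(z) & !is.na(r2)
  if (!is.null(candidate) && !include_candidate)
    keep <- keep & snp != candidate
  z <- z[keep]; r2 <- r2[keep]; snp <- snp[keep]
  if (any(r2 < -1e-9 | r2 > 1 + 1e-9)) stop("r2 values must lie in [0, 1]")
  r2 <- pmin(pmax(r2, 0), 1)
  if (length(z) < 3) stop("need at least 3 points for a fit")
  pts <- data.frame(snp = snp, sqrt_r2 = sqrt(r2), abs_z = abs(z),
                    stringsAsFactors = FALSE)
  fit <- stats::lm(abs_z ~ sqrt_r2, data = pts)
  co <- summary(fit)$coefficients
  structure(list(
    candidate = candidate %||% NA_character_, n_snps = nrow(pts),
    slope = unname(co["sqrt_r2", "Estimate"]),
    intercept = unname(co["(Intercept)", "Estimate"]),
    slope_se = unname(co["sqrt_r2", "Std. Error"]),
    intercept_se = unname(co["(Intercept)", "Std. Error"]),
    points = pts), class = "consistency_fit")
}

#' @export
print.consistency_fit <- function(x, ...) {
  cat(sprintf("<consistency_fit> candidate %s: slope %.3f (se %.3f), intercept %.3f (se %.3f), %d SNPs\n",
              x$candidate, x$slope, x$slope_se, x$intercept, x$intercept_se,
              x$n_snps))
  invisible(x)
}

#' Compare candidate causal SNPs by consistency slope
#'
#' For each candidate, computes EM-based r-squared between the candidate
#' and every SNP of the window, fits [consistency_fit()] over the shared
#' per-SNP Z-scores, and returns the fits sorted by slope (descending):
#' the candidate most consistent with being causal, or with perfectly
#' proxying the causal variant, has the largest slope.
#'
#' @param gm a [genotype_matrix()] with phenotype labels.
#' @param candidates vector of candidate SNP names (must lie in the
#'   window).
#' @param window SNP names of the reanalysis window (default: all SNPs).
#' @param include_candidate passed to [consistency_fit()].
#' @return named list of `consistency_fit` objects sorted by slope.
#' @export
compare_candidates <- function(gm, candidates, window = NULL,
                               include_candidate = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  window <- window %||% colnames(gm$genotypes)
  if (!all(candidates %in% window))
    stop("all candidates must lie within the window")
  zt <- per_snp_logistic_z(gm, window)
  z <- stats::setNames(ifelse(zt$estimable, zt$z, NA_real_), zt$snp)
  fits <- lapply(candidates, function(cand) {
    r2 <- vapply(window, function(s)
      if (s == cand) 1 else ld_stats(gm, cand, s, ci = FALSE)$r2,
      numeric(1))
    consistency_fit(z, r2[zt$snp], candidate = cand,
                    include_candidate = include_candidate)
  })
  names(fits) <- candidates
  fits[order(-vapply(fits, `[[`, numeric(1), "slope"))]
}
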