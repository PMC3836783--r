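#' LD correlation matrix from reference genotypes
#'
#' Pairwise Pearson correlations of genotype dosages (pairwise-complete
#' observations), repaired to the nearest positive-semidefinite matrix by
#' flooring eigenvalues at 1e-8 and re-normalizing to a unit diagonal.
#' Pairwise computation over incomplete data can produce indefinite
#' matrices, which would break the Cholesky factor of the simulation null.
#' SNPs with zero dosage variance in the reference are dropped with a
#' warning.
#'
#' @param gm a [genotype_matrix()] or dosage matrix (the LD reference).
#' @param snps column indices or names (default all).
#' @return correlation matrix with attribute `dropped` (names of
#'   zero-variance SNPs removed).
#' @export
ld_correlation_matrix <- function(gm, snps = NULL) {
  g <- if (inherits(gm, "genotype_matrix")) gm$genotypes else as.matrix(gm)
  if (nrow(g) < 2) stop("reference needs >= 2 samples")
  snps <- snps %||% seq_len(ncol(g))
  if (is.character(snps)) snps <- match(snps, colnames(g))
  g <- g[, snps, drop = FALSE]
  v <- apply(g, 2, stats::var, na.rm = TRUE)
  dropped <- colnames(g)[is.na(v) | v == 0]
  if (length(dropped)) {
    warning("dropping zero-variance SNP(s): ", paste(dropped, collapse = ", "))
    g <- g[, !(colnames(g) %in% dropped), drop = FALSE]
  }
  if (ncol(g) == 0) stop("no polymorphic SNPs left")
  C <- stats::cor(g, use = "pairwise.complete.obs")
  C[is.na(C)] <- 0
  diag(C) <- 1
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) < 1e-8) {
    vals <- pmax(e$values, 1e-8)
    C <- e$vectors %*% (vals * t(e$vectors))
    C <- stats::cov2cor(C)
  }
  dimnames(C) <- list(colnames(g), colnames(g))
  attr(C, "dropped") <- dropped
  C
}

#' Simulation-based gene-level association test
#'
#' The gene statistic is the sum of per-SNP 1-df chi-square statistics.
#' Its null distribution is simulated by drawing multivariate-normal
#' vectors `z ~ N(0, corr)` (via the Cholesky factor of the repaired LD
#' matrix) and summing their squares, so between-marker LD is carried into
#' the null. The empirical P-value uses the add-one correction
#' `(exceedances + 1) / (n_sims + 1)` and therefore lies in (0, 1].
#'
#' @param per_snp_chi2 vector of per-SNP chi-square statistics (1 df).
#' @param corr LD correlation matrix from [ld_correlation_matrix()]
#'   matching `per_snp_chi2` in order and length.
#' @param n_sims number of null simulations (default one million; fewer
#'   than 1000 triggers a resolution warning).
#' @param seed optional integer seed.
#' @param gene optional gene label carried into the result.
#' @param chunk simulation batch size (memory control).
#' @return an object of class `gene_test_result`: list with `gene`,
#'   `n_snps`, `observed_T`, `n_sims`, `empirical_p`, `seed`.
#' @export
gene_test <- function(per_snp_chi2, corr, n_sims = 1e6, seed = NULL,
                      gene = NA_character_, chunk = 1e5) {
  k <- length(per_snp_chi2)
  if (!is.matrix(corr) || nrow(corr) != k || ncol(corr) != k)
    stop("corr must be a k x k matrix matching per_snp_chi2")
  if (n_sims < 1000)
    warning("n_sims < 1000 gives poor empirical P resolution")
  if (!is.null(seed)) set.seed(seed)
  observed_T <- sum(per_snp_chi2)
  R <- tryCatch(chol(corr), error = function(e)
    chol(corr + diag(1e-6, k)))
  n_sims <- as.integer(n_sims)
  exceed <- 0L
  done <- 0L
  while (done < n_sims) {
    b <- min(chunk, n_sims - done)
    Z <- matrix(stats::rnorm(b * k), b, k) %*% R
    exceed <- exceed + sum(rowSums(Z * Z) >= observed_T)
    done <- done + b
  }
  structure(list(gene = gene, n_snps = k, observed_T = observed_T,
                 n_sims = n_sims, empirical_p = (exceed + 1) / (n_sims + 1),
                 seed = seed),
            class = "gene_test_result")
}

#' @export
print.gene_test_result <- function(x, ...) {
  cat(sprintf("<gene_test_result> %s: %d SNPs, T = %.3f, empirical P = %.3g (%d sims)\n",
              x$gene, x$n_snps, x$observed_T, x$empirical_p, x$n_sims))
  invisible(x)
}

#' Bonferroni threshold for gene-level tests
#'
#' `alpha / n_genes`; with the conventional 20,000 protein-coding genes
#' this is 2.5e-6.
#'
#' @param alpha family-wise error rate.
#' @param n_genes number of genes corrected for.
#' @return the per-gene significance threshold.
#' @export
bonferroni_gene_threshold <- function(alpha = 0.05, n_genes = 20000) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  alpha / n_genes
}
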