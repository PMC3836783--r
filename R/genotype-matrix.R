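#' Construct a genotype matrix object
#'
#' Container for a diploid case-control genotype set: a samples x SNPs
#' matrix of counted-allele dosages (0, 1, 2 or `NA` for missing), an
#' optional binary phenotype (1 = case, 0 = control) and per-SNP metadata.
#'
#' @param genotypes integer matrix, samples in rows, SNPs in columns;
#'   values must be 0, 1, 2 or `NA`. Row and column names are used as
#'   sample and SNP identifiers (generated when absent).
#' @param phenotype optional integer/numeric vector of 0/1 disease status,
#'   one per sample (`NA` allowed).
#' @param map optional data frame with one row per SNP and columns
#'   `chrom`, `snp`, `pos`, `a1` (counted allele) and `a2`. Defaults are
#'   generated when omitted.
#' @return an object of class `genotype_matrix`: a list with elements
#'   `genotypes`, `phenotype` and `map`.
#' @export
genotype_matrix <- function(genotypes, phenotype = NULL, map = NULL) {
  if (!is.matrix(genotypes)) genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  ok <- is.na(genotypes) | genotypes %in% 0:2
  if (!all(ok)) stop("genotypes must be coded 0/1/2 or NA")
  n <- nrow(genotypes); m <- ncol(genotypes)
  if (is.null(rownames(genotypes)))
    rownames(genotypes) <- sprintf("S%04d", seq_len(n))
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- sprintf("snp_%04d", seq_len(m))
  if (!is.null(phenotype)) {
    if (length(phenotype) != n)
      stop("phenotype length must equal number of samples")
    phenotype <- as.integer(phenotype)
    if (!all(is.na(phenotype) | phenotype %in% 0:1))
      stop("phenotype must be 0 (control), 1 (case) or NA")
  }
  if (is.null(map)) {
    map <- data.frame(
      chrom = "1", snp = colnames(genotypes),
      pos = 1000L * seq_len(m), a1 = "C", a2 = "A",
      stringsAsFactors = FALSE
    )
  } else {
    need <- c("chrom", "snp", "pos", "a1", "a2")
    if (!all(need %in% names(map)))
      stop("map must have columns ", paste(need, collapse = ", "))
    if (nrow(map) != m) stop("map must have one row per SNP")
    map$snp <- as.character(map$snp)
    colnames(genotypes) <- map$snp
  }
  structure(list(genotypes = genotypes, phenotype = phenotype, map = map),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  n <- nrow(x$genotypes); m <- ncol(x$genotypes)
  cat(sprintf("<genotype_matrix> %d samples x %d SNPs\n", n, m))
  if (!is.null(x$phenotype))
    cat(sprintf("  cases: %d  controls: %d\n",
                sum(x$phenotype == 1, na.rm = TRUE),
                sum(x$phenotype == 0, na.rm = TRUE)))
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param gm a `genotype_matrix`.
#' @param samples sample indices or names (default all).
#' @param snps SNP indices or names (default all).
#' @return the subset `genotype_matrix`.
#' @export
gm_subset <- function(gm, samples = NULL, snps = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  si <- samples %||% seq_len(nrow(gm$genotypes))
  vi <- snps %||% seq_len(ncol(gm$genotypes))
  if (is.character(vi)) vi <- match(vi, colnames(gm$genotypes))
  if (anyNA(vi)) stop("unknown SNP id in subset")
  genotype_matrix(gm$genotypes[si, vi, drop = FALSE],
                  phenotype = if (!is.null(gm$phenotype)) gm$phenotype[si],
                  map = gm$map[vi, , drop = FALSE])
}

#' Minor allele frequency of a dosage vector
#'
#' Frequency of the rarer allele, computed from non-missing dosages.
#'
#' @param g vector of 0/1/2 dosages (`NA` allowed).
#' @return frequency in `[0, 0.5]`, or `NA` if all missing.
#' @export
maf <- function(g) {
  f <- mean(g, na.rm = TRUE) / 2
  if (is.nan(f)) return(NA_real_)
  min(f, 1 - f)
}
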