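#' Variant caller configuration
#'
#' Threshold-based per-sample SNP calling parameters. A site is emitted when
#' its depth lies in `[min_coverage, max_coverage]` and the fraction of
#' reads supporting the best non-reference allele is at least
#' `het_alt_fraction`; the call is heterozygous below `hom_alt_fraction`
#' and homozygous-alternative at or above it. The upper genotype boundary
#' is a symmetric complement of the heterozygote threshold: only the
#' heterozygote cut-off is a published convention, so the boundary is
#' configurable.
#'
#' @param min_coverage minimum depth (reads), default 20.
#' @param max_coverage maximum depth; `Inf` by default, typically set
#'   per sample from [max_coverage_threshold()].
#' @param het_alt_fraction minimum alternative-read fraction for any call.
#' @param hom_alt_fraction boundary between het and hom-alt calls.
#' @param read_length read length in bp (used when deriving max coverage).
#' @return an object of class `caller_config`.
#' @export
caller_config <- function(min_coverage = 20, max_coverage = Inf,
                          het_alt_fraction = 0.35, hom_alt_fraction = 0.65,
                          read_length = 50) {
  if (min_coverage < 1) stop("min_coverage must be >= 1")
  if (!(het_alt_fraction > 0 && het_alt_fraction < hom_alt_fraction &&
        hom_alt_fraction <= 1))
    stop("need 0 < het_alt_fraction < hom_alt_fraction <= 1")
  structure(list(min_coverage = min_coverage, max_coverage = max_coverage,
                 het_alt_fraction = het_alt_fraction,
                 hom_alt_fraction = hom_alt_fraction,
                 read_length = read_length),
            class = "caller_config")
}

#' Theoretical highest average coverage for a sample
#'
#' The per-sample maximum-coverage threshold: total sequenced bases
#' (`n_reads * read_length`) divided by the length of the sequenced region.
#' Depth comparisons use `depth <= threshold` on the real-valued result.
#'
#' @param n_reads number of reads generated for the sample.
#' @param read_length read length in bp.
#' @param region_length length of the sequenced region in bp (> 0).
#' @return the threshold in reads (real-valued).
#' @export
max_coverage_threshold <- function(n_reads, read_length = 50, region_length) {
  if (region_length <= 0) stop("region_length must be > 0")
  n_reads * read_length / region_length
}

pileup_count_cols <- c("count_A", "count_C", "count_G", "count_T")

validate_pileup <- function(pileup) {
  need <- c("sample", "chrom", "pos", "ref", "depth", pileup_count_cols)
  if (!all(need %in% names(pileup)))
    stop("pileup must have columns ", paste(need, collapse = ", "))
  if (nrow(pileup) == 0) return(invisible(pileup))
  cnt <- as.matrix(pileup[, pileup_count_cols])
  bad <- which(rowSums(cnt) != pileup$depth | !(pileup$ref %in% c("A", "C", "G", "T")))
  if (length(bad))
    stop(sprintf("malformed pileup row %d: allele counts do not sum to depth or bad ref allele",
                 bad[1]))
  invisible(pileup)
}

#' Call SNPs from per-sample pileup allele counts
#'
#' Applies the coverage and alternative-allele-fraction thresholds of a
#' [caller_config()] to each pileup row. The alternative allele is the most
#' frequent non-reference allele, ties broken alphabetically. Output order
#' follows (sample, chrom, pos), so the calls are invariant to input row
#' order.
#'
#' @param pileup data frame in the pileup layout of [simulate_pileups()]
#'   (may hold one or several samples).
#' @param config a [caller_config()].
#' @return data frame of calls: `sample`, `chrom`, `pos`, `ref`, `alt`,
#'   `depth`, `alt_count`, `alt_fraction`, `genotype` (`"het"`/`"hom_alt"`).
#' @export
call_sample_variants <- function(pileup, config = caller_config()) {
  stopifnot(inherits(config, "caller_config"))
  validate_pileup(pileup)
  empty <- data.frame(sample = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      depth = integer(), alt_count = integer(),
                      alt_fraction = numeric(), genotype = character(),
                      stringsAsFactors = FALSE)
  if (nrow(pileup) == 0) return(empty)
  bases <- c("A", "C", "G", "T")
  cnt <- as.matrix(pileup[, pileup_count_cols])
  colnames(cnt) <- bases
  cnt[cbind(seq_len(nrow(cnt)), match(pileup$ref, bases))] <- -1L
  alt_idx <- max.col(cnt, ties.method = "first")  # alphabetical tie-break
  alt_count <- cnt[cbind(seq_len(nrow(cnt)), alt_idx)]
  alt_count[alt_count < 0L] <- 0L
  alt_fraction <- ifelse(pileup$depth > 0, alt_count / pileup$depth, 0)
  keep <- pileup$depth >= config$min_coverage &
    pileup$depth <= config$max_coverage &
    alt_fraction >= config$het_alt_fraction
  out <- data.frame(
    sample = pileup$sample[keep], chrom = pileup$chrom[keep],
    pos = pileup$pos[keep], ref = pileup$ref[keep],
    alt = bases[alt_idx[keep]], depth = pileup$depth[keep],
    alt_count = alt_count[keep], alt_fraction = alt_fraction[keep],
    genotype = ifelse(alt_fraction[keep] < config$hom_alt_fraction,
                      "het", "hom_alt"),
    stringsAsFactors = FALSE
  )
  out[order(out$sample, out$chrom, out$pos), , drop = FALSE]
}

#' Merge per-sample calls into a cohort-level site set
#'
#' Takes the union of called sites across samples and computes a cohort
#' allele frequency per site: samples with a call contribute 1 (het) or 2
#' (hom-alt) alternative alleles; samples without a call but with depth at
#' or above `min_coverage` at the site are counted as homozygous reference;
#' samples below `min_coverage` are treated as missing.
#'
#' @param calls data frame of calls from [call_sample_variants()].
#' @param pileups the cohort pileups (used for callable-depth lookups).
#' @param min_coverage callable-depth threshold (reads).
#' @return data frame, one row per site: `chrom`, `pos`, `ref`, `alt`,
#'   `n_alt_alleles`, `n_called_samples`, `n_missing`, `alt_freq`, `maf`.
#' @export
merge_calls <- function(calls, pileups, min_coverage = 20) {
  empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), n_alt_alleles = integer(),
                      n_called_samples = integer(), n_missing = integer(),
                      alt_freq = numeric(), maf = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(calls) || nrow(calls) == 0) return(empty)
  validate_pileup(pileups)
  samples <- unique(pileups$sample)
  site_key <- paste(calls$chrom, calls$pos)
  refs <- tapply(calls$ref, site_key, function(r) length(unique(r)))
  if (any(refs > 1))
    stop("conflicting reference alleles at site ", names(refs)[refs > 1][1])
  pk <- paste(pileups$sample, pileups$chrom, pileups$pos)
  depth_lut <- pileups$depth
  names(depth_lut) <- pk

  sites <- unique(calls[, c("chrom", "pos")])
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  res <- lapply(seq_len(nrow(sites)), function(i) {
    ch <- sites$chrom[i]; po <- sites$pos[i]
    here <- calls$chrom == ch & calls$pos == po
    alt_per_sample <- ifelse(calls$genotype[here] == "het", 1L, 2L)
    names(alt_per_sample) <- calls$sample[here]
    other <- setdiff(samples, names(alt_per_sample))
    d <- depth_lut[paste(other, ch, po)]
    d[is.na(d)] <- 0
    n_ref_callable <- sum(d >= min_coverage)
    n_missing <- length(other) - n_ref_callable
    n_nonmiss <- length(alt_per_sample) + n_ref_callable
    n_alt <- sum(alt_per_sample)
    f <- if (n_nonmiss > 0) n_alt / (2 * n_nonmiss) else NA_real_
    data.frame(chrom = ch, pos = po, ref = calls$ref[here][1],
               alt = calls$alt[here][1], n_alt_alleles = n_alt,
               n_called_samples = length(alt_per_sample),
               n_missing = n_missing, alt_freq = f,
               maf = min(f, 1 - f), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Coverage summary over target regions
#'
#' Per region (BED convention: 0-based half-open intervals) the mean depth
#' and the percentage of sample-basepairs covered at >= 10x and >= 20x,
#' with unreported basepairs counted as depth 0. When the pileups hold
#' several samples, percentages are over all sample-basepairs.
#'
#' @param pileups cohort pileup data frame (1-based `pos`).
#' @param regions data frame with `chrom`, `start` (0-based), `end`,
#'   `name`.
#' @param n_samples number of samples the region was sequenced in;
#'   defaults to the number of distinct samples in `pileups`.
#' @return data frame: `name`, `chrom`, `start`, `end`, `mean_depth`,
#'   `pct_bp_ge_10x`, `pct_bp_ge_20x`.
#' @export
coverage_summary <- function(pileups, regions, n_samples = NULL) {
  if (nrow(regions) == 0) stop("regions must be non-empty")
  n_samples <- n_samples %||% length(unique(pileups$sample))
  out <- lapply(seq_len(nrow(regions)), function(i) {
    ch <- regions$chrom[i]; s <- regions$start[i]; e <- regions$end[i]
    len <- (e - s) * max(n_samples, 1)
    sel <- pileups$chrom == ch & pileups$pos > s & pileups$pos <= e
    d <- pileups$depth[sel]
    if (n_samples == 0 || len == 0) {
      md <- 0; p10 <- 0; p20 <- 0
    } else {
      md <- sum(d) / len
      p10 <- 100 * sum(d >= 10) / len
      p20 <- 100 * sum(d >= 20) / len
    }
    data.frame(name = regions$name[i], chrom = ch, start = s, end = e,
               mean_depth = md, pct_bp_ge_10x = p10, pct_bp_ge_20x = p20,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
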