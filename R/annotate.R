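#' Annotate called sites against known-variant lists and gene models
#'
#' Each site receives exactly one discovery category with precedence
#' `known_db` > `panel_only` > `novel`, a functional class from gene-model
#' interval overlap with precedence exon > UTR > intron (no overlap =
#' intergenic; exonic sites are classed `exonic_unspecified` because codon
#' frames are not modelled), a minor-allele-frequency bin and a gene label.
#'
#' @param sites data frame with `chrom`, `pos`, `alt` and optionally `maf`
#'   (e.g. output of [merge_calls()]).
#' @param known_db,panel data frames of known sites with `chrom`, `pos`
#'   and, when `match_alleles = TRUE`, `alt`.
#' @param gene_model data frame of intervals with `chrom`, `start`
#'   (0-based), `end`, `gene`, `class` (`"exon"`, `"utr"`, `"intron"`).
#' @param match_alleles require position AND alternative-allele match when
#'   looking a site up in the known lists (default); `FALSE` matches on
#'   position only.
#' @return `sites` with added columns `category`, `functional_class`,
#'   `gene`, `maf_bin`.
#' @export
annotate_sites <- function(sites, known_db = NULL, panel = NULL,
                           gene_model = NULL, match_alleles = TRUE) {
  key <- function(d) {
    if (match_alleles && !is.null(d$alt)) paste(d$chrom, d$pos, d$alt)
    else paste(d$chrom, d$pos)
  }
  sk <- key(sites)
  in_db <- if (!is.null(known_db) && nrow(known_db)) sk %in% key(known_db) else
    rep(FALSE, nrow(sites))
  in_panel <- if (!is.null(panel) && nrow(panel)) sk %in% key(panel) else
    rep(FALSE, nrow(sites))
  sites$category <- ifelse(in_db, "known_db",
                           ifelse(in_panel, "panel_only", "novel"))

  cls <- rep("intergenic", nrow(sites))
  gene <- rep(NA_character_, nrow(sites))
  if (!is.null(gene_model) && nrow(gene_model)) {
    prec <- c(exon = 1L, utr = 2L, intron = 3L)
    warned <- FALSE
    for (i in seq_len(nrow(sites))) {
      hit <- gene_model$chrom == sites$chrom[i] &
        sites$pos[i] > gene_model$start & sites$pos[i] <= gene_model$end
      if (!any(hit)) next
      classes <- gene_model$class[hit]
      if (length(unique(classes)) > 1 && !warned) {
        warning("overlapping gene-model intervals with different classes; using precedence exon > utr > intron")
        warned <- TRUE
      }
      best <- which.min(prec[classes])
      cls[i] <- c(exon = "exonic_unspecified", utr = "utr",
                  intron = "intronic")[classes[best]]
      gene[i] <- gene_model$gene[hit][best]
    }
  }
  sites$functional_class <- cls
  sites$gene <- gene
  sites$maf_bin <- if (!is.null(sites$maf)) maf_bin(sites$maf) else NA_character_
  sites
}

#' Bin minor allele frequencies
#'
#' Bins are `[0, 0.05)` = `"lt5"`, `[0.05, 0.10]` = `"5to10"`,
#' `(0.10, 0.5]` = `"gt10"` — the boundary values 0.05 and 0.10 fall in the
#' middle bin.
#'
#' @param f numeric vector of minor allele frequencies.
#' @return character vector of bin labels.
#' @export
maf_bin <- function(f) {
  ifelse(is.na(f), NA_character_,
         ifelse(f < 0.05, "lt5", ifelse(f <= 0.10, "5to10", "gt10")))
}

#' Per-gene discovery summary
#'
#' Tabulates annotated sites per gene: counts by discovery category and
#' functional class, plus minor-allele-frequency bin percentages, with a
#' grand-total row whose counts equal the column sums.
#'
#' @param annotated output of [annotate_sites()].
#' @param per_gene optional character vector of gene labels overriding the
#'   `gene` column (must cover all sites).
#' @return data frame, one row per gene plus a `"total"` row.
#' @export
discovery_summary <- function(annotated, per_gene = NULL) {
  gene <- per_gene %||% annotated$gene
  gene[is.na(gene)] <- "other"
  cols <- c("detected", "known_db", "panel_only", "novel",
            "exonic", "intronic", "utr", "intergenic",
            "pct_maf_lt5", "pct_maf_5to10", "pct_maf_gt10")
  if (nrow(annotated) == 0) {
    out <- as.data.frame(as.list(stats::setNames(rep(0, length(cols)), cols)))
    return(cbind(data.frame(gene = "total", stringsAsFactors = FALSE), out))
  }
  one <- function(idx) {
    a <- annotated[idx, , drop = FALSE]
    n <- nrow(a)
    pct <- function(bin)
      if (all(is.na(a$maf_bin))) NA_real_ else
        round_half_up(100 * sum(a$maf_bin == bin, na.rm = TRUE) / n, 1)
    data.frame(
      detected = n,
      known_db = sum(a$category == "known_db"),
      panel_only = sum(a$category == "panel_only"),
      novel = sum(a$category == "novel"),
      exonic = sum(a$functional_class == "exonic_unspecified"),
      intronic = sum(a$functional_class == "intronic"),
      utr = sum(a$functional_class == "utr"),
      intergenic = sum(a$functional_class == "intergenic"),
      pct_maf_lt5 = pct("lt5"), pct_maf_5to10 = pct("5to10"),
      pct_maf_gt10 = pct("gt10")
    )
  }
  genes <- sort(unique(gene))
  rows <- lapply(genes, function(g) one(which(gene == g)))
  out <- cbind(data.frame(gene = genes, stringsAsFactors = FALSE),
               do.call(rbind, rows))
  total <- cbind(data.frame(gene = "total", stringsAsFactors = FALSE),
                 one(seq_len(nrow(annotated))))
  rbind(out, total)
}

#' Add a grand-total row to a per-gene counts table
#'
#' For pre-tabulated per-gene discovery counts (one row per gene, numeric
#' count columns), appends a `"total"` row of column sums.
#'
#' @param counts data frame with a `gene` column and numeric columns.
#' @return `counts` with a final `"total"` row.
#' @export
discovery_totals <- function(counts) {
  num <- vapply(counts, is.numeric, logical(1))
  tot <- counts[1, , drop = FALSE]
  tot[1, !num] <- NA
  tot$gene <- "total"
  tot[1, num] <- as.list(colSums(counts[, num, drop = FALSE]))
  rbind(counts, tot)
}

#' Capture-design coverage percentage
#'
#' Percentage of a target region represented on a capture design,
#' `100 * covered / region`, rounded half-up to one decimal.
#'
#' @param region_length total region length (any unit, e.g. kb).
#' @param covered_length length covered on the design (same unit).
#' @return percentage with one decimal.
#' @export
capture_design_coverage <- function(region_length, covered_length) {
  if (region_length <= 0) stop("region_length must be > 0")
  if (covered_length < 0 || covered_length > region_length)
    stop("covered_length must lie in [0, region_length]")
  round_half_up(100 * covered_length / region_length, 1)
}

#' On-target read percentage
#'
#' `100 * mapped / total`, rounded half-up to the nearest integer.
#'
#' @param mapped reads mapping to the region of interest.
#' @param total total reads generated.
#' @return integer percentage.
#' @export
mapped_read_percentage <- function(mapped, total) {
  if (total <= 0) stop("total must be > 0")
  if (mapped < 0 || mapped > total) stop("mapped must lie in [0, total]")
  round_half_up(100 * mapped / total, 0)
}
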