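#' Read a PED/MAP text genotype file pair
#'
#' PLINK-style text pedigree format: the MAP file has four columns
#' (chromosome, SNP id, genetic distance, bp position); the PED file has
#' six leading columns (FID, IID, PAT, MAT, SEX, PHENOTYPE) followed by
#' two allele columns per SNP, with `"0"` encoding a missing allele.
#' Phenotypes 1/2 map to control/case; 0 and -9 map to missing. The
#' counted allele per SNP is the minor allele in the file (alphabetical
#' tie-break), so a write/read round trip preserves dosages whenever the
#' counted allele is the rarer one.
#'
#' @param ped_path,map_path file paths.
#' @return a [genotype_matrix()].
#' @export
read_ped_map <- function(ped_path, map_path) {
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp", "cm", "pos"))
  m <- nrow(map)
  want <- 6 + 2 * m
  cf <- utils::count.fields(ped_path)
  bad <- which(cf != want)
  if (length(bad))
    stop(sprintf("PED parse error at line %d: %d fields, expected %d",
                 bad[1], cf[bad[1]], want))
  ped <- utils::read.table(ped_path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  n <- nrow(ped)
  phe_raw <- ped[[6]]
  phenotype <- ifelse(phe_raw == "2", 1L, ifelse(phe_raw == "1", 0L, NA))
  geno <- matrix(NA_integer_, n, m)
  a1 <- character(m); a2 <- character(m)
  for (j in seq_len(m)) {
    al1 <- ped[[6 + 2 * j - 1]]
    al2 <- ped[[6 + 2 * j]]
    miss <- al1 == "0" | al2 == "0"
    alleles <- c(al1[!miss], al2[!miss])
    if (length(alleles) == 0) { a1[j] <- "0"; a2[j] <- "0"; next }
    tab <- sort(table(alleles))
    levs <- names(tab)
    if (length(levs) > 2)
      stop("SNP ", map$snp[j], " has more than two alleles")
    if (length(levs) == 2 && tab[1] == tab[2]) levs <- sort(levs)
    a1[j] <- levs[1]
    a2[j] <- if (length(levs) == 2) levs[2] else levs[1]
    geno[, j] <- (al1 == a1[j]) + (al2 == a1[j])
    geno[miss, j] <- NA
  }
  rownames(geno) <- make.unique(ped[[2]])
  genotype_matrix(geno,
                  phenotype = if (all(is.na(phenotype))) NULL else phenotype,
                  map = data.frame(chrom = as.character(map$chrom),
                                   snp = map$snp, pos = map$pos,
                                   a1 = a1, a2 = a2,
                                   stringsAsFactors = FALSE))
}

#' Write a genotype matrix as PED/MAP text files
#'
#' Inverse of [read_ped_map()]: dosage 2 becomes `a1 a1`, 1 becomes
#' `a1 a2`, 0 becomes `a2 a2` and missing becomes `0 0`; phenotype 1/0
#' is written as 2/1 (missing as 0).
#'
#' @param gm a [genotype_matrix()].
#' @param prefix output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.map`.
#' @return the two file paths, invisibly.
#' @export
write_ped_map <- function(gm, prefix) {
  stopifnot(inherits(gm, "genotype_matrix"))
  g <- gm$genotypes; map <- gm$map
  n <- nrow(g); m <- ncol(g)
  phe <- if (is.null(gm$phenotype)) rep(0L, n) else
    ifelse(is.na(gm$phenotype), 0L, gm$phenotype + 1L)
  allele_cols <- matrix("0", n, 2 * m)
  for (j in seq_len(m)) {
    gj <- g[, j]
    c1 <- ifelse(is.na(gj), "0", ifelse(gj >= 1, map$a1[j], map$a2[j]))
    c2 <- ifelse(is.na(gj), "0", ifelse(gj == 2, map$a1[j], map$a2[j]))
    allele_cols[, 2 * j - 1] <- c1
    allele_cols[, 2 * j] <- c2
  }
  ped <- cbind(rownames(g), rownames(g), "0", "0", "0", phe, allele_cols)
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  utils::write.table(ped, ped_path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(data.frame(map$chrom, map$snp, 0, map$pos),
                     map_path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(c(ped = ped_path, map = map_path))
}

#' Write variant calls as a minimal VCF 4.2 file
#'
#' Per-sample calls (from [call_sample_variants()]) become sample columns
#' with GT:DP:AD fields; a merged site set (from [merge_calls()]) becomes
#' a site-only VCF with the cohort allele frequency in INFO/AF. Sites are
#' sorted by chromosome and position on write, with a warning when the
#' input was unsorted. An empty input yields a header-only file.
#'
#' @param x calls or merged-site data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=candseq",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Cohort alternative allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele read depths\">")
  per_sample <- "sample" %in% names(x)
  if (nrow(x)) {
    ord <- order(x$chrom, x$pos)
    if (!identical(ord, seq_len(nrow(x))))
      warning("sites were unsorted; sorted on write")
    x <- x[ord, , drop = FALSE]
  }
  if (per_sample) {
    samples <- sort(unique(x$sample))
    cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", samples)
    sites <- unique(x[, c("chrom", "pos", "ref", "alt")])
    body <- vapply(seq_len(nrow(sites)), function(i) {
      here <- x$chrom == sites$chrom[i] & x$pos == sites$pos[i]
      per <- x[here, , drop = FALSE]
      cells <- vapply(samples, function(s) {
        r <- per[per$sample == s, , drop = FALSE]
        if (nrow(r) == 0) return("./.")
        gt <- if (r$genotype[1] == "hom_alt") "1/1" else "0/1"
        sprintf("%s:%d:%d,%d", gt, r$depth[1],
                r$depth[1] - r$alt_count[1], r$alt_count[1])
      }, character(1))
      paste(c(sites$chrom[i], sites$pos[i], ".", sites$ref[i],
              sites$alt[i], ".", "PASS", ".", "GT:DP:AD", cells),
            collapse = "\t")
    }, character(1))
  } else {
    cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
    body <- if (nrow(x)) vapply(seq_len(nrow(x)), function(i)
      paste(c(x$chrom[i], x$pos[i], ".", x$ref[i], x$alt[i], ".", "PASS",
              sprintf("AF=%.6g", x$alt_freq[i])), collapse = "\t"),
      character(1)) else character(0)
  }
  writeLines(c(header, paste(cols, collapse = "\t"), body), path)
  invisible(path)
}

#' Read a site list from VCF or a two-column TSV
#'
#' Known-variant lists (reference database or panel) are accepted either
#' as VCF (parsed with the vcfR package) or as a headered TSV with at
#' least `chrom` and `pos` columns (optionally `alt`).
#'
#' @param path input path; treated as VCF when it ends in `.vcf`.
#' @return data frame with `chrom`, `pos` and (when available) `alt`.
#' @export
read_known_sites <- function(path) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("reading VCF site lists requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- v@fix  # always a matrix, even for a single variant
    return(data.frame(chrom = as.character(fix[, "CHROM"]),
                      pos = as.integer(fix[, "POS"]),
                      alt = as.character(fix[, "ALT"]),
                      stringsAsFactors = FALSE))
  }
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos") %in% names(d)))
    stop("site list TSV needs 'chrom' and 'pos' columns")
  d
}

#' Read and write pileup TSV files
#'
#' Tab-separated pileup tables with one row per sample-site and columns
#' `sample`, `chrom`, `pos`, `ref`, `depth`, `count_A`, `count_C`,
#' `count_G`, `count_T`. The reader validates that allele counts sum to
#' depth and names the offending line otherwise.
#'
#' @param path file path.
#' @return `read_pileup`: the validated pileup data frame.
#' @export
read_pileup <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  tryCatch(validate_pileup(d), error = function(e)
    stop("in ", path, ": ", conditionMessage(e)))
  d
}

#' @rdname read_pileup
#' @param pileup pileup data frame to write.
#' @export
write_pileup <- function(pileup, path) {
  utils::write.table(pileup, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a BED interval file
#'
#' Plain BED (0-based half-open) with at least chrom/start/end and an
#' optional name column; a name of the form `gene:class` is split into
#' `gene` and `class` columns (used for gene-model feature intervals).
#'
#' @param path file path.
#' @return data frame with `chrom`, `start`, `end`, `name` and, when the
#'   name encodes it, `gene` and `class`.
#' @export
read_bed <- function(path) {
  d <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  names(d)[1:3] <- c("chrom", "start", "end")
  d$chrom <- as.character(d$chrom)
  if (ncol(d) >= 4) {
    names(d)[4] <- "name"
    has_class <- grepl(":", d$name, fixed = TRUE)
    if (any(has_class)) {
      parts <- strsplit(d$name, ":", fixed = TRUE)
      d$gene <- vapply(parts, `[`, character(1), 1)
      d$class <- vapply(parts, function(p) p[2] %||% NA_character_,
                        character(1))
    }
  } else {
    d$name <- sprintf("region_%d", seq_len(nrow(d)))
  }
  d
}

#' Write a BED interval file
#'
#' @param regions data frame with `chrom`, `start`, `end` and optionally
#'   `name`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(regions))
  utils::write.table(regions[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
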