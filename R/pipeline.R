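#' Pipeline configuration
#'
#' Declarative configuration for [run_pipeline()]: simulation design,
#' caller/QC thresholds (defaulting to the conventional values used
#' throughout the package), analysis sizes and stage toggles. The object
#' round-trips losslessly through YAML via [write_pipeline_config()] /
#' [read_pipeline_config()].
#'
#' @param n_snps,ld_rho,maf_range,n_cases,n_controls,causal_index,odds_ratio,prevalence
#'   simulation design (see [make_haplotype_pool()] and [cohort_spec()]).
#' @param n_discovery number of (control) samples sequenced for variant
#'   discovery.
#' @param mean_depth,error_rate,read_length pileup simulation parameters.
#' @param snp_missing_rate,sample_missing_rate injected missingness rates.
#' @param min_coverage,het_alt_fraction,hom_alt_fraction caller thresholds.
#' @param on_target_fraction fraction of reads on target, used to scale
#'   the per-sample theoretical-maximum-coverage threshold (off-target
#'   reads inflate a sample's read total without raising on-target depth).
#' @param qc QC thresholds as a named list matching [qc_config()]
#'   arguments.
#' @param n_genes number of gene groups the SNP panel is split into.
#' @param gene_test_sims simulations per gene-level test.
#' @param block_snps how many SNPs (from the panel start) enter block
#'   construction.
#' @param epi_focal,epi_partner numbers of focal and partner SNPs for the
#'   epistasis scan.
#' @param candidates candidate SNP indices for the consistency stage
#'   (default: the causal SNP when present, else the top-association SNP).
#' @param seed master seed; each stage derives its own stream from it.
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "call", "qc", "assoc", "blocks", "genetest",
#'   "epistasis", "consistency")`.
#' @return an object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(n_snps = 200, ld_rho = 0.8,
                            maf_range = c(0.05, 0.45),
                            n_cases = 2000, n_controls = 2000,
                            causal_index = 100, odds_ratio = 1.3,
                            prevalence = 0.1, n_discovery = 50,
                            mean_depth = 30, error_rate = 0.01,
                            read_length = 50,
                            snp_missing_rate = 0.02,
                            sample_missing_rate = 0.02,
                            min_coverage = 20, het_alt_fraction = 0.35,
                            hom_alt_fraction = 0.65,
                            on_target_fraction = 0.27,
                            qc = list(), n_genes = 3,
                            gene_test_sims = 1e4, block_snps = 12,
                            epi_focal = 4, epi_partner = 8,
                            candidates = NULL, seed = 1,
                            stages = c("simulate", "call", "qc", "assoc",
                                       "blocks", "genetest", "epistasis",
                                       "consistency")) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("config files require the yaml package")
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("config files require the yaml package")
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, raw[names(raw) %in%
                                        names(formals(pipeline_config))])
  cfg
}

#' Run the full analysis chain on a synthetic cohort
#'
#' Mirrors the stage order of a resequencing fine-mapping study: simulate
#' (pool, cohort, discovery pileups, missingness) -> call -> QC ->
#' single-SNP association -> LD blocks and haplotype association ->
#' gene-level simulation test -> epistasis scan -> causal-consistency
#' reanalysis. Each stage logs its parameters and input/output counts to
#' the returned report; when `out_dir` is given, stage tables are written
#' there as TSV. A stage failure aborts downstream stages but preserves
#' the partial report.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for stage TSVs.
#' @return a report: named list of per-stage summaries plus `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(d, name) {
    if (!is.null(out_dir))
      utils::write.table(d, file.path(out_dir, paste0(name, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report <- list(config = unclass(config))
  on.exit(return(report))
  run <- function(stage) stage %in% config$stages
  log_msg <- function(...) message("[candseq] ", sprintf(...))

  gm <- NULL; pool <- NULL
  if (run("simulate")) {
    log_msg("simulate: %d SNPs, rho %.2f, %d+%d cohort, OR %.2f",
            config$n_snps, config$ld_rho, config$n_cases, config$n_controls,
            config$odds_ratio)
    pool <- make_haplotype_pool(20000, config$n_snps, config$ld_rho,
                                config$maf_range, seed = config$seed)
    spec <- cohort_spec(config$n_cases, config$n_controls,
                        causal_index = config$causal_index,
                        odds_ratio = config$odds_ratio,
                        prevalence = config$prevalence,
                        seed = config$seed + 1L)
    gm <- simulate_cohort(pool, spec)
    gm <- inject_missingness(gm, snp_rate = config$snp_missing_rate,
                             sample_rate = config$sample_missing_rate,
                             seed = config$seed + 2L)
    report$simulate <- list(n_snps = ncol(gm$genotypes),
                            n_samples = nrow(gm$genotypes),
                            seed = config$seed)
  }
  if (run("call") && !is.null(gm)) {
    disc <- which(gm$phenotype == 0)[seq_len(config$n_discovery)]
    disc_gm <- gm_subset(gm, samples = disc)
    pile <- simulate_pileups(disc_gm, config$mean_depth, config$error_rate,
                             config$read_length, seed = config$seed + 3L)
    calls <- do.call(rbind, lapply(unique(pile$sample), function(s) {
      p <- pile[pile$sample == s, , drop = FALSE]
      # assayed sites stand in for the sequenced region; a sample's read
      # total is its on-target bases inflated by the off-target fraction
      region_len <- nrow(p)
      n_reads <- sum(p$depth) / config$read_length / config$on_target_fraction
      cfg <- caller_config(
        min_coverage = config$min_coverage,
        max_coverage = max_coverage_threshold(n_reads, config$read_length,
                                              region_len),
        het_alt_fraction = config$het_alt_fraction,
        hom_alt_fraction = config$hom_alt_fraction)
      call_sample_variants(p, cfg)
    }))
    merged <- merge_calls(calls, pile, config$min_coverage)
    emit(merged, "called_sites")
    log_msg("call: %d per-sample calls, %d merged sites",
            nrow(calls), nrow(merged))
    report$call <- list(n_discovery = length(disc),
                        n_calls = nrow(calls), n_sites = nrow(merged))
  }
  if (run("qc") && !is.null(gm)) {
    qc_cfg <- do.call(qc_config, config$qc)
    res <- qc_filter(gm, qc_cfg)
    emit(res$report, "qc_exclusions")
    log_msg("qc: %d exclusions, %d SNPs retained",
            nrow(res$report), ncol(res$genotypes$genotypes))
    report$qc <- list(n_excluded = nrow(res$report),
                      n_snps = ncol(res$genotypes$genotypes),
                      n_samples = nrow(res$genotypes$genotypes),
                      rates = genotyping_rate_report(gm)$overall)
    gm <- res$genotypes
  }
  assoc <- NULL
  if (run("assoc") && !is.null(gm) && ncol(gm$genotypes) > 0) {
    assoc <- assoc_scan(gm)
    emit(assoc, "association")
    top <- assoc[which.min(assoc$p), ]
    log_msg("assoc: top %s P = %.3g OR = %.3f", top$snp, top$p,
            top$odds_ratio)
    report$assoc <- list(n_snps = nrow(assoc), top_snp = top$snp,
                         top_p = top$p, top_or = top$odds_ratio)
  }
  if (run("blocks") && !is.null(gm) && ncol(gm$genotypes) >= 3) {
    k <- min(config$block_snps, ncol(gm$genotypes))
    lp <- ld_matrix(gm, seq_len(k))
    blocks <- build_blocks(lp, k, positions = gm$map$pos[seq_len(k)])
    hap <- lapply(blocks, function(b)
      haplotype_association(gm, b$snps))
    block_p <- vapply(hap, `[[`, numeric(1), "block_p")
    report$blocks <- list(n_blocks = length(blocks),
                          block_p = block_p,
                          best_p = if (length(block_p)) min(block_p) else NA)
    log_msg("blocks: %d block(s), best haplotype P = %.3g",
            length(blocks), report$blocks$best_p)
  }
  if (run("genetest") && !is.null(assoc)) {
    genes <- split(seq_len(nrow(assoc)),
                   cut(seq_len(nrow(assoc)), config$n_genes,
                       labels = sprintf("gene%d", seq_len(config$n_genes))))
    gt <- lapply(names(genes), function(gname) {
      idx <- genes[[gname]]
      corr <- ld_correlation_matrix(gm, idx)
      keep <- match(rownames(corr), gm$map$snp[idx])
      gene_test(assoc$chi2[idx][keep], corr, n_sims = config$gene_test_sims,
                seed = config$seed + 10L, gene = gname)
    })
    res <- data.frame(gene = vapply(gt, `[[`, character(1), "gene"),
                      n_snps = vapply(gt, `[[`, numeric(1), "n_snps"),
                      observed_T = vapply(gt, `[[`, numeric(1), "observed_T"),
                      n_sims = vapply(gt, `[[`, numeric(1), "n_sims"),
                      empirical_p = vapply(gt, `[[`, numeric(1), "empirical_p"))
    emit(res, "gene_tests")
    report$genetest <- list(table = res,
                            threshold = bonferroni_gene_threshold())
    log_msg("genetest: best gene P = %.3g", min(res$empirical_p))
  }
  if (run("epistasis") && !is.null(gm) &&
      ncol(gm$genotypes) >= config$epi_focal + config$epi_partner) {
    snps <- colnames(gm$genotypes)
    focal <- snps[seq_len(config$epi_focal)]
    partner <- snps[seq(length(snps) - config$epi_partner + 1, length(snps))]
    scan <- gene_group_scan(gm, focal, partner)
    emit(scan$results, "epistasis")
    report$epistasis <- scan$summary
    log_msg("epistasis: %d tests, min P = %.3g", scan$summary$n_tests,
            if (!is.null(scan$summary$top)) scan$summary$top$p else NA)
  }
  if (run("consistency") && !is.null(gm) && ncol(gm$genotypes) >= 4) {
    cand_idx <- config$candidates %||%
      (if (!is.null(assoc)) which.min(assoc$p) else 1L)
    cands <- colnames(gm$genotypes)[cand_idx]
    fits <- compare_candidates(gm, cands)
    report$consistency <- lapply(fits, function(f)
      list(candidate = f$candidate, slope = f$slope,
           slope_se = f$slope_se, intercept = f$intercept,
           n_snps = f$n_snps))
    emit(do.call(rbind, lapply(fits, function(f)
      data.frame(candidate = f$candidate, slope = f$slope,
                 intercept = f$intercept, slope_se = f$slope_se,
                 intercept_se = f$intercept_se, n_snps = f$n_snps))),
      "consistency")
    log_msg("consistency: top candidate %s slope %.2f",
            fits[[1]]$candidate, fits[[1]]$slope)
  }
  on.exit()
  report
}
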