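#' Exact conditional Hardy-Weinberg test
#'
#' Exact test conditioning on the observed allele counts: the P-value is
#' the sum of probabilities of all heterozygote counts (with the same
#' allele totals) whose probability does not exceed that of the observed
#' configuration. Probabilities are evaluated in log space, so cohort-scale
#' counts are handled without overflow. Departures from equilibrium in
#' controls are the standard signal of genotyping error in association QC.
#'
#' @param n_hom_major,n_het,n_hom_minor genotype counts (>= 0, total > 0).
#' @return the exact P-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_major, n_het, n_hom_minor) {
  counts <- c(n_hom_major, n_het, n_hom_minor)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0) stop("total genotype count must be > 0")
  rare <- 2 * min(n_hom_major, n_hom_minor) + n_het
  if (rare == 0) return(1)

  # feasible heterozygote counts share the parity of the rare-allele total
  h <- seq(rare %% 2, min(rare, 2 * n - rare), by = 2)
  lp <- lfactorial(n) - lfactorial((rare - h) / 2) - lfactorial(h) -
    lfactorial(n - (rare + h) / 2) + h * log(2) +
    lfactorial(rare) + lfactorial(2 * n - rare) - lfactorial(2 * n)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_het, h)]
  if (is.na(p_obs)) stop("observed heterozygote count infeasible for allele totals")
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}
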