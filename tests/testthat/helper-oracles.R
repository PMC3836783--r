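# Independent oracles used by several test files.

# full-enumeration exact HWE P-value: direct conditional probabilities of
# every feasible heterozygote count given the allele totals
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  nA <- 2 * n_aa + n_ab
  nB <- 2 * n_bb + n_ab
  rare <- min(nA, nB)
  hs <- seq(rare %% 2, min(rare, 2 * n - rare), by = 2)
  pr <- vapply(hs, function(h) {
    a <- (rare - h) / 2
    b <- n - a - h
    exp(lgamma(n + 1) - lgamma(a + 1) - lgamma(h + 1) - lgamma(b + 1) +
          h * log(2) -
          (lgamma(2 * n + 1) - lgamma(rare + 1) - lgamma(2 * n - rare + 1)))
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[hs == n_ab]
  sum(pr[pr <= obs * (1 + 1e-12)])
}
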