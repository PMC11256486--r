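# Independent brute-force oracles used across test files.

# Exhaustive two-sided Fisher p: enumerate all 2x2 tables with the observed
# margins and sum hypergeometric probabilities <= the observed table's
# (minimum-likelihood convention, with the customary 1e-7 relative slack
# when comparing probabilities).
fisher_two_sided_oracle <- function(k, K, n, N) {
  m <- k + n                      # identifiers carrying the term
  lo <- max(0, m - N)
  hi <- min(m, K)
  probs <- dhyper(lo:hi, K, N, m)
  p_obs <- dhyper(k, K, N, m)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
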