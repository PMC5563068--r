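# Shared fixtures, all built in code.

# 20-point robustness fixture: ten observations at 0 and ten at
# 0.01, ..., 0.10.  A single-component moment fit of it has a known
# closed form (computed in the tests from the moment equations).
toy_data <- function() c(rep(0, 10), seq(0.01, 0.10, by = 0.01))

random_beta_params <- function(lo = 0.2, hi = 50) {
  beta_params(stats::runif(1, lo, hi), stats::runif(1, lo, hi))
}

# A random dataset containing exact 0s and 1s, plus its generating model.
random_boundary_dataset <- function(n = 100) {
  truth <- gen_methylation_mixture()
  clamp_extremes(sample_mixture(truth, n), k = max(1L, n %/% 50))
}
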