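# shared helpers for the test suite

rel_diff <- function(a, b) {
  abs(a - b) / pmax(abs(a), abs(b), .Machine$double.eps)
}

# random positive state respecting nothing but nonnegativity (for RHS checks)
random_state <- function(network, seed) {
  withr::with_seed(seed, {
    stats::setNames(stats::runif(length(network$species)), network$species)
  })
}

# small Latin-hypercube of valid parameter draws around a preset, used by
# solver cross-checks; stays well inside the default exploration ranges
random_param_draws <- function(n, seed, params = gq_params("initial")) {
  rng <- default_ranges(params, half_decades = 1)
  sample_parameter_sets(rng, scheme = "lhs", n_base = n, seed = seed)
}
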