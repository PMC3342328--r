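# Shared fixtures: the canonical parameter set used throughout (N = 5000,
# r0 = 0.9, delta = 0.05, a = 0.5, for which rbar* = 0.8, beta = 2,
# n0* = 1250), plus a fast-extinction set for persistence-time tests.

canonical_params <- function(n_cells = 5000, seed = 1) {
  model_params(n_cells = n_cells, r0 = 0.9, delta = 0.05,
               apoptosis_prob = 0.5, seed = seed)
}

fast_extinction_params <- function(seed = 1) {
  model_params(n_cells = 50, r0 = 0.5, delta = 0.25, apoptosis_prob = 0.6,
               seed = seed)
}
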