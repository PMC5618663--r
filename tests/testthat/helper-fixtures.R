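# Shared fixtures: small, fast study-condition variants built in code.

# short live-cell-style experiment for unit tests
short_truth <- function(seed, noisy = FALSE) default_truth(seed, noisy = noisy)

# single-species truth (no B, no population dynamics): every cycle identical
single_species_truth <- function(seed, k = 5, c = 0) {
  ground_truth(
    kinetics = two_state_kinetics(k_A = k, k_B = k / 100, f_A = 0, f_B = 0,
                                  c = c),
    popdyn = popdyn_params(k_AB = 0, k_dA = 0, k_dB = 0, a0 = 1, b0 = 0),
    noise = noise_model(),
    seed = seed)
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected) / abs(expected)), tol)
}
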