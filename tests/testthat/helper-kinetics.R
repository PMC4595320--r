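# Shared fixtures: the acetylornithine-aminotransferase-style reaction
# (m = p = 2, Keq = 1.7281) and its reference parameter values.

arg8_spec <- function() reaction_spec(2, 2, keq = 1.7281)

arg8_truth <- function() kinetic_params(2.5783, 3.7327, 3.5238)

# sigma ~ 0 stand-in for noiseless fitting (the likelihood needs sigma > 0)
tiny_noise <- function() noise_model(1e-6, 1e-6, 1e-6)

noiseless_data <- function(n = 30, seed = 1, spec = arg8_spec(),
                           truth = arg8_truth()) {
  simulate_experiments(truth, spec, design_spec(n), noise_model(0, 0, 0),
                       seed = seed)
}

noiseless_mm_data <- function(c1 = 1.5, c2 = 0.8, keq = 1, n = 12, seed = 1) {
  simulate_mm_experiments(c1, c2, keq, n, noise = noise_model(0, 0, 0),
                          seed = seed)
}

rel_err <- function(x, ref) abs(x - ref) / abs(ref)
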