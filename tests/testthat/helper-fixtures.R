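# shared fixtures: simulate per-state patterns and build noiseless mixtures

state_patterns <- function(peptide, states, mode = "nominal") {
  lapply(seq_len(nrow(states)), function(i)
    simulate_pattern(labeled_composition(peptide, states[i, ]), mode = mode))
}

# noiseless synthetic mixture + everything needed to refit it
make_mixture <- function(peptide, scheme, weights, seed = 1, noise = 0,
                         resolving_power = 80000, mode = "nominal",
                         points_per_Da = if (mode == "fine") 10000 else 1000,
                         extras = list()) {
  sp <- synth_spec(peptide, scheme, weights = weights,
                   resolving_power = resolving_power, noise_sd = noise,
                   points_per_Da = points_per_Da, seed = seed, mode = mode,
                   extras = extras)
  g <- generate_spectrum(sp)
  g$patterns <- state_patterns(peptide, g$truth$states, mode = mode)
  g
}
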