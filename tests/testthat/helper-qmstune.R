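# Shared fixtures, built in code.

# Noise-free default instrument.
quiet_instrument <- function(...) {
  virtual_instrument(noise_cv = 0, ...)
}

# Two-parameter instrument for brute-force grid oracles. `opt` defaults to
# values lying exactly on a 10-level grid over [0, 9].
tiny_instrument <- function(opt = c(A = 3, B = 7), sigma = c(2, 2),
                            interaction = FALSE, rho = 0.6, noise_cv = 0) {
  virtual_instrument(
    parameters = data.frame(name = names(opt), lower = 0, upper = 9,
                            opt = unname(opt), sigma = sigma),
    peaks = default_peaks()[1, ],
    noise_cv = noise_cv, mca = 1L,
    interaction = interaction, interaction_rho = rho,
    interaction_pair = names(opt))
}

sphere <- function(x) sum(x^2)
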