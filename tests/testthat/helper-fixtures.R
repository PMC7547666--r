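# Shared fixtures, generated in code.

# Reduced-scale benchmark spectra: p = 300 wavelengths (1000-1299 cm-1),
# two analyte bands (1090 and 1230 cm-1) on a broad background, 47-sample
# concentration grid. The default noise floor puts the stronger band at a
# signal-to-noise ratio of about 12 at the top of the concentration range,
# low enough that averaging over a band genuinely helps a calibration.
reduced_sim <- function(seed = 7, noise_sd = 6e-3, drift = 5e-4,
                        bg_var = 0.02) {
  generate_spectra(sim_config(
    wavenumber_start = 1000, wavenumber_end = 1299,
    analyte_peaks = data.frame(center = c(1090, 1230), width = c(12, 9),
                               height = c(0.004, 0.003)),
    background_peaks = data.frame(center = 1150, width = 80, height = 0.5),
    background_amplitude_sd = bg_var,
    noise_sd = noise_sd, baseline_drift_amplitude = drift, seed = seed))
}

# Small latent-structure regression problem: y = X w + noise with a single
# informative direction.
latent_problem <- function(n = 30, p = 20, noise = 0.05, seed = 3) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  w <- c(2, rep(0, p - 1L))
  list(X = X, y = drop(X %*% w) + rnorm(n, sd = noise), w = w)
}
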