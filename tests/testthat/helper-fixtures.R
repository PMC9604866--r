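# Shared fixtures: small, fast variants of the study defaults.

quick_pulse <- function() pulse_params()

# Forward model without artifact or noise: echoes only.
clean_forward <- function(...) {
  forward_model_params(artifact_amplitude = 0, noise_sigma = 0, ...)
}

# A 3 x 3 SAR-guided-style aperture centered on the default tumor direction.
default_aperture <- function(phantom = make_default_phantom()) {
  plan_aperture(phantom$tumors[[1]]$center, phantom)
}

# Simulated cancerous/tumor-free pair on the default phantom.
simulated_pair <- function(phantom = make_default_phantom(),
                           geometry = default_aperture(phantom),
                           params = forward_model_params(),
                           pulse = quick_pulse()) {
  list(tb = simulate_scan(phantom, geometry, pulse, params,
                          with_tumors = TRUE),
       b = simulate_scan(phantom, geometry, pulse, params,
                         with_tumors = FALSE))
}

# Small imaging config for unit tests (pitch ~0.8 mm).
small_config <- function(...) imaging_config(n_x = 128, n_y = 128, ...)
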