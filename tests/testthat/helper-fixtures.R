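# Shared fixtures: small geometries and quiet simulation configs used across
# the unit tests. Everything is generated in code at test time.

# fully-live square mini detector, integer-friendly center
mini_geometry <- function(n = 32L, pixel = 2.7e-4, center = NULL) {
  if (is.null(center)) center <- c(n / 2 - 0.5, n / 2 - 0.5)
  detector_geometry(distance = 0.130, pixel_size = pixel, wavelength = 0.729,
                    shape = c(n, n), beam_center = center,
                    panel_mask = matrix(TRUE, n, n))
}

# deterministic, noise-free simulation settings (no jitter, no contaminants)
quiet_sim <- function(seed = 1L, ...) {
  sim_config(seed = seed, fluence_jitter = 0, contaminant_fraction = 0,
             empty_fraction = 0, ...)
}

# two-block toy network for gradient and shape tests
tiny_model_config <- function() {
  model_config(input_size = c(8L, 8L), base_filters = 2L, max_filters = 4L,
               n_blocks = 2L, downsample_plan = list(c(2L, 2L), c(2L, 2L)),
               final_size = c(2L, 2L))
}
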