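# Shared phantom configurations for tests.  `tiny_phantom_config` keeps the
# study-condition geometry (layer levels, IMT, band thicknesses) but shrinks
# the frame count and width so per-test runtime stays small.

tiny_phantom_config <- function(...) {
  args <- list(width = 64, height = 160, n_frames = 8, frames_per_cycle = 8)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantom_config, args)
}

noise_layer_config <- function(cfg = phantom_config()) {
  phantom_config(subintima_noise = list(intensity = 0.45, thickness = 3,
                                        frames = systolic_frames(cfg)))
}
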