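# Small scene/stack builders shared across tests. Frames are kept small so
# the default suite stays fast; the synthetic model is identical at full
# sensor size.

tiny_shape <- c(64, 160)   # H x W

tiny_scene <- function(name = "flat", seed = 1L, H = tiny_shape[1],
                       speckle_contrast = 0.15, reference_column = 60, ...) {
  preset_scene(name, extent_y_um = H * 5.58, seed = seed,
               speckle_contrast = speckle_contrast,
               reference_column = reference_column, ...)
}

# Calibration fitted on a noiseless linear stack: exact 0.29 px/um truth.
linear_truth_calibration <- function(range_um = 200) {
  z <- seq(0, range_um, by = 2.5)
  build_calibration(z, 0.29 * z, degree = 1)
}

# The published-style degree-5 calibration polynomial used as a fixed
# regression instance (coefficients lowest order first).
printed_cal_coefficients <- c(-0.74, 0.29, 4.52e-5, -5.33e-7, 1.06e-9, -6.26e-13)

printed_calibration <- function() {
  calibration_from_coefficients(printed_cal_coefficients, c(0, 750))
}
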