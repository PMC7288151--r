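test_that("noiseless linear data is recovered exactly, even at degree 5", {
  z <- seq(0, 750, by = 2.5)   # 301 points
  cal <- build_calibration(z, 0.29 * z - 0.74, degree = 5)
  cf <- coef(cal)
  expect_equal(unname(cf["c0"]), -0.74, tolerance = 1e-9)
  expect_equal(unname(cf["c1"]), 0.29, tolerance = 1e-9)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)
  expect_equal(cal$valid_z_range, c(0, 750))
  expect_equal(cal$linear_slope, 0.29, tolerance = 1e-9)
})

test_that("a degree-5 polynomial is recovered from its own noiseless samples", {
  z <- seq(0, 750, by = 2.5)
  dn <- lsmtopo:::polyval(printed_cal_coefficients, z)
  cal <- build_calibration(z, dn, degree = 5)
  expect_equal(unname(coef(cal)), printed_cal_coefficients, tolerance = 1e-6)
})

test_that("build_calibration validates its inputs", {
  expect_error(build_calibration(c(0, 1, 2), c(0, 1, 2), degree = 5),
               "degree \\+ 2")
  expect_error(build_calibration(c(0, 2, 1), c(0, 1, 2), degree = 1),
               "strictly increasing")
  expect_error(build_calibration(1:10, 1:9, degree = 1))
})

test_that("a non-monotone fit warns and restricts inversion", {
  z <- seq(0, 100, by = 5)
  dn <- 1 * z - 0.006 * z^2    # increasing only up to z ~ 83
  expect_warning(cal <- build_calibration(z, dn, degree = 2),
                 "not strictly increasing")
  expect_false(cal$monotone)
  expect_lt(cal$invertible_z_range[2], 90)
  # inversion still works on the increasing part
  expect_equal(invert_offset(cal, predict_offset(cal, 40)), 40,
               tolerance = 1e-5)
})

test_that("predict_offset evaluates the polynomial and checks its domain", {
  cal <- printed_calibration()
  expect_equal(predict_offset(cal, 0), -0.74)
  expect_equal(predict_offset(cal, 72), 20.202651, tolerance = 1e-6)
  cal2 <- calibration_from_coefficients(c(0, 0.3), c(0, 750))
  expect_equal(predict_offset(cal2, 100), 30)
  expect_error(predict_offset(cal, 800), "outside the calibrated range")
  expect_error(predict_offset(cal, -5), "outside the calibrated range")
})

test_that("invert_offset is the exact inverse of predict_offset", {
  cal <- printed_calibration()
  zs <- seq(10, 750, length.out = 100)
  z_back <- invert_offset(cal, predict_offset(cal, zs))
  expect_equal(z_back, zs, tolerance = 1e-5)
  # frozen independent roots of the printed polynomial
  expect_equal(invert_offset(cal, 21), 74.753203, tolerance = 1e-4)
  expect_equal(invert_offset(cal, 20), 71.300591, tolerance = 1e-4)
  # linear model: (36 + 0.74) / 0.29
  lin <- calibration_from_coefficients(c(-0.74, 0.29), c(0, 750))
  expect_equal(invert_offset(lin, 36), 126.689655, tolerance = 1e-5)
  expect_error(invert_offset(cal, 1e5), "attainable")
})

test_that("z resolution bound is the step times the guaranteed-shift count", {
  expect_equal(z_resolution_bound(2.5, 4), 10)
  expect_equal(z_resolution_bound(2.5, 1), 2.5)
  expect_equal(z_resolution_bound(5, 3), 15)
  expect_error(z_resolution_bound(0, 4))
})

test_that("nonlinear part of the printed polynomial is small next to the linear term", {
  cf <- printed_cal_coefficients
  z <- seq(10, 750, by = 1)
  nonlin <- lsmtopo:::polyval(cf, z) - (cf[1] + cf[2] * z)
  expect_lt(max(abs(nonlin) / abs(cf[2] * z)), 0.10)
})

test_that("end-to-end synthetic calibration recovers the forward slope", {
  # the height range and row count must give the degree-5 fit enough
  # leverage to pin down c1; 151 steps of 5 um mirror the instrument
  # protocol's 750 um span at reduced frame size
  sc <- tiny_scene("flat", seed = 21, H = 160, speckle_contrast = 0.15,
                   reference_column = 40)
  frames <- render_calibration_stack(sc, n_steps = 151, step_um = 5,
                                     image_shape = c(160, 320))
  cal <- calibrate_stack(frames, step_um = 5, degree = 5)
  expect_lt(abs(cal$linear_slope - sc$pixels_per_um) / sc$pixels_per_um, 0.02)
  expect_gte(cal$r_squared, 0.999)
  # fitted model on linear-truth data: nonlinear part below 5% of linear term
  cf <- unname(coef(cal))
  z <- seq(10, 750, by = 1)
  nonlin <- lsmtopo:::polyval(cf, z) - (cf[1] + cf[2] * z)
  expect_lt(max(abs(nonlin) / abs(cf[2] * z)), 0.05)
})

test_that("fitted slope is unbiased and stable over seeded calibration runs", {
  slopes <- vapply(1:20, function(seed) {
    sc <- tiny_scene("flat", seed = 100 + seed, speckle_contrast = 0.15)
    frames <- render_calibration_stack(sc, n_steps = 21, step_um = 5,
                                       image_shape = c(48, 120))
    calibrate_stack(frames, step_um = 5, degree = 1)$linear_slope
  }, numeric(1))
  truth <- 0.29
  expect_lt(abs(mean(slopes) - truth) / truth, 0.01)   # relative bias < 1%
  expect_lt(stats::sd(slopes) / truth, 0.03)           # spread < 3%
})

test_that("calibration models round-trip through JSON", {
  z <- seq(0, 200, by = 2.5)
  cal <- build_calibration(z, 0.29 * z - 0.5 + 1e-4 * z^2, degree = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(cal, path, metadata = list(step_um = 2.5))
  back <- read_calibration(path)
  expect_equal(back$coefficients, cal$coefficients)
  expect_equal(back$valid_z_range, cal$valid_z_range)
  expect_equal(back$r_squared, cal$r_squared)
  zz <- seq(5, 195, length.out = 20)
  expect_equal(predict_offset(back, zz), predict_offset(cal, zz))
})

test_that("model methods report coefficients and residuals coherently", {
  z <- seq(0, 100, by = 5)
  set.seed(2)
  cal <- build_calibration(z, 0.29 * z + rnorm(length(z), sd = 0.05),
                           degree = 1)
  expect_named(coef(cal), c("c0", "c1"))
  expect_length(residuals(cal), length(z))
  expect_equal(mean(residuals(cal)), 0, tolerance = 1e-10)
  expect_output(print(cal), "linear slope")
  expect_equal(predict(cal, 50), predict_offset(cal, 50))
})
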