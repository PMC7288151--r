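#' Fit the pixel-offset-versus-height calibration polynomial
#'
#' Fits, by ordinary least squares, a polynomial mapping from stage height
#' offset `delta_z` (micrometres) to stripe pixel offset `delta_n` (pixels):
#' \deqn{\Delta n = c_0 + c_1 \Delta z + \dots + c_k \Delta z^k.}
#' The standard calibration protocol raises a flat surface in fixed
#' increments (e.g. 2.5 um over 301 frames), extracts the stripe contour of
#' each frame, and summarizes each frame's per-row offsets into one
#' `delta_n`; see [calibrate_stack()]. In the orthogonal triangulation
#' configuration the truth is linear, so `c_1` (pixels per micrometre) is the
#' physically meaningful slope and higher orders absorb residual distortion.
#'
#' @param delta_z Strictly increasing height offsets, micrometres.
#' @param delta_n Pixel offsets, one per height.
#' @param degree Polynomial degree (default 5; use 1 for the purely linear
#'   regime). Needs `length(delta_z) >= degree + 2`.
#' @return An object of class `"lsm_calibration"`: coefficients (lowest order
#'   first), `r_squared`, `valid_z_range`, `linear_slope` (`c_1`),
#'   monotonicity diagnostics, and the fitting data. If the fitted polynomial
#'   is not strictly increasing over the data range a warning is issued and
#'   inversion is restricted to the largest increasing subinterval.
#' @seealso [predict_offset()], [invert_offset()], [calibrate_stack()]
#' @examples
#' z <- seq(0, 750, by = 2.5)
#' cal <- build_calibration(z, 0.29 * z - 0.74, degree = 1)
#' coef(cal)
#' @export
build_calibration <- function(delta_z, delta_n, degree = 5) {
  stopifnot(is.numeric(delta_z), is.numeric(delta_n),
            length(delta_z) == length(delta_n))
  if (degree < 1) stop("degree must be at least 1")
  if (length(delta_z) < degree + 2)
    stop("need at least degree + 2 calibration points")
  if (any(diff(delta_z) <= 0))
    stop("delta_z values must be strictly increasing")
  fit <- stats::lm(delta_n ~ stats::poly(delta_z, degree, raw = TRUE))
  cf <- unname(stats::coef(fit))
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((delta_n - mean(delta_n))^2)
  r2 <- 1 - ss_res / ss_tot
  zr <- range(delta_z)
  mono <- monotone_range(cf, zr)
  if (!mono$monotone)
    warning("fitted polynomial is not strictly increasing over the ",
            "calibration range; inversion restricted to [",
            signif(mono$range[1], 6), ", ", signif(mono$range[2], 6), "] um")
  structure(list(
    coefficients = cf,
    degree = degree,
    r_squared = r2,
    valid_z_range = zr,
    linear_slope = cf[2],
    monotone = mono$monotone,
    invertible_z_range = mono$range,
    n_points = length(delta_z),
    data = data.frame(delta_z = delta_z, delta_n = delta_n)
  ), class = "lsm_calibration")
}

# Largest subinterval of zr (containing the midpoint where possible) on which
# the polynomial increases, from the sign of its derivative on a fine grid.
monotone_range <- function(cf, zr) {
  dcf <- cf[-1] * seq_len(length(cf) - 1)
  grid <- seq(zr[1], zr[2], length.out = 1024)
  deriv <- polyval(dcf, grid)
  if (all(deriv > 0)) return(list(monotone = TRUE, range = zr))
  ok <- deriv > 0
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  pos <- which(runs$values)
  if (length(pos) == 0) return(list(monotone = FALSE, range = c(NA, NA)))
  best <- pos[which.max(runs$lengths[pos])]
  list(monotone = FALSE, range = c(grid[starts[best]], grid[ends[best]]))
}

polyval <- function(cf, x) {
  # coefficients lowest order first; Horner
  out <- rep(cf[length(cf)], length(x))
  for (k in rev(seq_len(length(cf) - 1))) out <- out * x + cf[k]
  out
}

#' Construct a calibration model from known coefficients
#'
#' Wraps externally supplied polynomial coefficients (lowest order first)
#' into an `"lsm_calibration"` object, e.g. a published fit or a single
#' calibrated linear scale.
#'
#' @param coefficients Numeric vector `c0, c1, ...`, lowest order first.
#' @param valid_z_range Height interval (um) the coefficients are valid on.
#' @param r_squared Optional goodness of fit to record.
#' @return An `"lsm_calibration"`.
#' @examples
#' # a linear 0.29 px/um scale valid over [0, 750] um
#' calibration_from_coefficients(c(-0.74, 0.29), c(0, 750))
#' @export
calibration_from_coefficients <- function(coefficients, valid_z_range,
                                          r_squared = NA_real_) {
  stopifnot(is.numeric(coefficients), length(coefficients) >= 2,
            length(valid_z_range) == 2, valid_z_range[1] < valid_z_range[2])
  mono <- monotone_range(coefficients, valid_z_range)
  if (!mono$monotone)
    warning("polynomial is not strictly increasing over valid_z_range; ",
            "inversion restricted")
  structure(list(
    coefficients = unname(coefficients),
    degree = length(coefficients) - 1L,
    r_squared = r_squared,
    valid_z_range = as.numeric(valid_z_range),
    linear_slope = coefficients[2],
    monotone = mono$monotone,
    invertible_z_range = mono$range,
    n_points = 0L,
    data = NULL
  ), class = "lsm_calibration")
}

#' @export
print.lsm_calibration <- function(x, digits = 4, ...) {
  cat(sprintf("Light-sheet calibration: degree-%d polynomial dz (um) -> dn (px)\n",
              x$degree))
  cat("  coefficients (c0, c1, ...):",
      paste(signif(x$coefficients, digits), collapse = ", "), "\n")
  cat(sprintf("  linear slope c1 = %s px/um\n", signif(x$linear_slope, digits)))
  if (!is.na(x$r_squared))
    cat(sprintf("  R-squared = %s on %d points\n",
                signif(x$r_squared, 6), x$n_points))
  cat(sprintf("  valid dz range: [%g, %g] um%s\n",
              x$valid_z_range[1], x$valid_z_range[2],
              if (x$monotone) "" else " (non-monotone fit; inversion restricted)"))
  invisible(x)
}

#' @export
coef.lsm_calibration <- function(object, ...) {
  stats::setNames(object$coefficients, paste0("c", seq_along(object$coefficients) - 1))
}

#' @export
summary.lsm_calibration <- function(object, ...) {
  print(object)
  if (!is.null(object$data)) {
    res <- object$data$delta_n -
      polyval(object$coefficients, object$data$delta_z)
    cat(sprintf("  residuals (px): RMS %s, max |.| %s\n",
                signif(sqrt(mean(res^2)), 4), signif(max(abs(res)), 4)))
  }
  invisible(object)
}

#' @export
residuals.lsm_calibration <- function(object, ...) {
  if (is.null(object$data)) stop("model carries no fitting data")
  object$data$delta_n - polyval(object$coefficients, object$data$delta_z)
}

#' @export
predict.lsm_calibration <- function(object, delta_z, ...) {
  predict_offset(object, delta_z)
}

#' @export
plot.lsm_calibration <- function(x, ...) {
  if (is.null(x$data)) stop("model carries no fitting data")
  graphics::plot(x$data$delta_z, x$data$delta_n, pch = 16, cex = 0.4,
                 xlab = expression(Delta * z ~ "(um)"),
                 ylab = expression(Delta * n ~ "(px)"), ...)
  zz <- seq(x$valid_z_range[1], x$valid_z_range[2], length.out = 400)
  graphics::lines(zz, polyval(x$coefficients, zz), col = 2)
  invisible(x)
}

#' Predict a pixel offset from a height offset
#'
#' Evaluates the calibration polynomial at `delta_z`.
#'
#' @param model An `"lsm_calibration"`.
#' @param delta_z Height offsets, micrometres, inside the model's
#'   `valid_z_range`.
#' @return Pixel offsets.
#' @export
predict_offset <- function(model, delta_z) {
  stopifnot(inherits(model, "lsm_calibration"))
  zr <- model$valid_z_range
  if (any(delta_z < zr[1] - 1e-9 | delta_z > zr[2] + 1e-9))
    stop("delta_z outside the calibrated range [", zr[1], ", ", zr[2], "] um")
  polyval(model$coefficients, delta_z)
}

#' Invert the calibration: height offset from a pixel offset
#'
#' Finds the unique `delta_z` with `predict_offset(model, delta_z) ==
#' delta_n` by bracketed root-finding on the (restricted-to-monotone)
#' calibration range, to an absolute tolerance of 1e-6 um. Vectorized over
#' `delta_n`.
#'
#' `extend_um` allows mild polynomial extrapolation beyond the calibrated
#' range (applied only where the polynomial remains increasing). This
#' matters at the lower end: measurement noise scatters offsets
#' symmetrically around the reference, and refusing to invert slightly
#' negative offsets would rectify that noise into a positive bias on
#' zero-height surfaces.
#'
#' @param model An `"lsm_calibration"`.
#' @param delta_n Pixel offsets within the image of the (extended)
#'   invertible range.
#' @param extend_um Extrapolation allowance beyond each end of the
#'   calibrated range, micrometres (default 0: strict).
#' @return Height offsets, micrometres.
#' @export
invert_offset <- function(model, delta_n, extend_um = 0) {
  stopifnot(inherits(model, "lsm_calibration"), extend_um >= 0)
  zr <- model$invertible_z_range
  if (any(is.na(zr))) stop("calibration is nowhere invertible")
  cf <- model$coefficients
  if (extend_um > 0) {
    dcf <- cf[-1] * seq_len(length(cf) - 1)
    lo <- seq(zr[1] - extend_um, zr[1], length.out = 64)
    if (all(polyval(dcf, lo) > 0)) zr[1] <- zr[1] - extend_um
    hi <- seq(zr[2], zr[2] + extend_um, length.out = 64)
    if (all(polyval(dcf, hi) > 0)) zr[2] <- zr[2] + extend_um
  }
  n_lo <- polyval(cf, zr[1])
  n_hi <- polyval(cf, zr[2])
  if (any(delta_n < n_lo - 1e-9 | delta_n > n_hi + 1e-9))
    stop("delta_n outside the attainable range [", signif(n_lo, 6), ", ",
         signif(n_hi, 6), "] px")
  vapply(delta_n, function(dn) {
    if (dn <= n_lo) return(zr[1])
    if (dn >= n_hi) return(zr[2])
    stats::uniroot(function(z) polyval(cf, z) - dn, interval = zr,
                   tol = 1e-9)$root
  }, numeric(1))
}

#' Guaranteed height resolution along the optical axis
#'
#' With a calibration acquired in increments of `step_um`, speckle noise can
#' leave the stripe stationary over single increments; if
#' `steps_to_guaranteed_shift` increments are always enough to move the
#' stripe by at least one pixel, the guaranteed height resolution is their
#' product. With 2.5 um steps and a shift guaranteed after 4 steps the bound
#' is 10 um.
#'
#' @param step_um Calibration step, micrometres (> 0).
#' @param steps_to_guaranteed_shift Number of steps after which a >= 1 px
#'   stripe shift is always observed (>= 1).
#' @return Resolution bound, micrometres.
#' @examples
#' z_resolution_bound(2.5, 4)  # 10
#' @export
z_resolution_bound <- function(step_um, steps_to_guaranteed_shift) {
  stopifnot(step_um > 0, steps_to_guaranteed_shift >= 1)
  step_um * steps_to_guaranteed_shift
}

#' Calibrate from a stack of flat-surface frames
#'
#' Runs the full calibration protocol on an ordered list of frames of a flat
#' surface raised in fixed increments: smooth each frame, extract its stripe
#' contour, summarize the per-row stripe positions into one column per frame
#' (median over valid rows by default), subtract the first frame's column,
#' and fit the offset polynomial.
#'
#' @param frames List of [lsm_image()] frames in acquisition order.
#' @param step_um Height increment between consecutive frames, micrometres.
#' @param degree Polynomial degree for [build_calibration()].
#' @param summary `"median"` (default, robust to residual speckle) or
#'   `"mean"`: how a frame's per-row positions collapse to one value.
#' @param smooth Logical; apply [smooth_image()] first (default TRUE).
#' @param radius,eps Guided-filter parameters, see [smooth_image()].
#' @return An `"lsm_calibration"` whose `valid_z_range` is
#'   `[0, (n_frames - 1) * step_um]`.
#' @export
calibrate_stack <- function(frames, step_um, degree = 5,
                            summary = c("median", "mean"), smooth = TRUE,
                            radius = 4, eps = NULL) {
  summary <- match.arg(summary)
  stopifnot(length(frames) >= 2, step_um > 0)
  sfun <- if (summary == "median") stats::median else mean
  cols <- vapply(frames, function(fr) {
    if (smooth) fr <- smooth_image(fr, radius = radius, eps = eps)
    ct <- extract_contour(fr)
    sfun(ct$column_position[ct$valid])
  }, numeric(1))
  dz <- (seq_along(frames) - 1) * step_um
  build_calibration(dz, cols - cols[1], degree = degree)
}

#' Serialize a calibration model to JSON
#'
#' @param model An `"lsm_calibration"`.
#' @param path Output path.
#' @param metadata Optional named list stored alongside the fit (e.g. step
#'   size, frame count).
#' @return `path`, invisibly.
#' @export
write_calibration <- function(model, path, metadata = list()) {
  stopifnot(inherits(model, "lsm_calibration"))
  obj <- list(
    coefficients = model$coefficients,
    degree = model$degree,
    r_squared = model$r_squared,
    valid_z_range = model$valid_z_range,
    metadata = metadata
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a calibration model written by [write_calibration()]
#'
#' @param path JSON path.
#' @return An `"lsm_calibration"`.
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_from_coefficients(obj$coefficients, obj$valid_z_range,
                                r_squared = obj$r_squared %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
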