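#' Select a contour arc in physical coordinates
#'
#' Converts a row range of a stripe contour into `(y, z)` points in
#' micrometres: `y` from the row index through the lateral scale, `z` from
#' the stripe offset through the inverse calibration — the per-axis physical
#' scales that let a circle be fit in real units rather than pixels.
#'
#' @param profile An [extract_contour()] result.
#' @param row_range `c(first, last)` image rows of the curved section
#'   (selected by eye, as is conventional).
#' @param lateral_scale_um Micrometres per image row.
#' @param calibration An `"lsm_calibration"`.
#' @param reference_column Stripe column of zero height; default
#'   [reference_column()] of the profile's valid rows outside `row_range`.
#' @return Data frame with columns `y`, `z` (micrometres); >= 3 rows.
#' @export
select_arc <- function(profile, row_range, lateral_scale_um, calibration,
                       reference_column = NULL) {
  stopifnot(inherits(profile, "lsm_contour"), length(row_range) == 2,
            lateral_scale_um > 0, inherits(calibration, "lsm_calibration"))
  if (is.null(reference_column)) {
    outside <- profile$valid &
      (profile$row < row_range[1] | profile$row > row_range[2])
    if (!any(outside))
      stop("no rows outside row_range to derive a reference column from; ",
           "pass reference_column explicitly")
    reference_column <- stats::median(profile$column_position[outside])
  }
  keep <- profile$valid & profile$row >= row_range[1] &
    profile$row <= row_range[2]
  if (sum(keep) < 3) stop("fewer than 3 valid rows in row_range")
  dn <- profile$column_position[keep] - reference_column
  zr <- calibration$invertible_z_range
  n_rng <- polyval(calibration$coefficients, zr)
  dn <- pmin(pmax(dn, n_rng[1]), n_rng[2])
  data.frame(
    y = (profile$row[keep] - 1) * lateral_scale_um,
    z = invert_offset(calibration, dn)
  )
}

#' Least-squares circle fit
#'
#' Fits a circle to `(y, z)` points in two stages: an algebraic fit (the
#' linear least-squares system in `y^2 + z^2`, which has a closed-form
#' solution and no starting-point problem) followed by geometric refinement
#' minimizing the sum of squared radial distances `(dist_i - R)^2` over the
#' centre (for a fixed centre the optimal radius is the mean distance).
#'
#' @param points Data frame or matrix with columns `y` and `z` (micrometres);
#'   at least 3 non-collinear points.
#' @param refine Logical; run the geometric refinement stage (default TRUE).
#' @return An object of class `"lsm_circlefit"`: `center_y`, `center_z`,
#'   `radius` (micrometres), `rms_residual` (micrometres), `n_points`.
#' @examples
#' th <- seq(0, pi / 3, length.out = 50)
#' fit_circle(data.frame(y = 100 * cos(th), z = 100 * sin(th)))
#' @export
fit_circle <- function(points, refine = TRUE) {
  pts <- as.data.frame(points)
  stopifnot(all(c("y", "z") %in% names(pts)))
  y <- pts$y; z <- pts$z
  n <- length(y)
  if (n < 3) stop("need at least 3 points")
  # algebraic (Kasa) stage: y^2 + z^2 = 2 a y + 2 b z + c
  A <- cbind(2 * y, 2 * z, 1)
  rhs <- y^2 + z^2
  qra <- qr(A)
  if (qra$rank < 3)
    stop("points are collinear: circle radius is infinite")
  sol <- qr.coef(qra, rhs)
  cy <- sol[1]; cz <- sol[2]
  r2 <- sol[3] + cy^2 + cz^2
  if (!is.finite(r2) || r2 <= 0)
    stop("points are collinear or degenerate: no finite circle")
  if (refine) {
    obj <- function(p) {
      d <- sqrt((y - p[1])^2 + (z - p[2])^2)
      sum((d - mean(d))^2)
    }
    opt <- stats::optim(c(cy, cz), obj, method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 500))
    cy <- opt$par[1]; cz <- opt$par[2]
  }
  d <- sqrt((y - cy)^2 + (z - cz)^2)
  radius <- mean(d)
  if (!is.finite(radius) || radius <= 0)
    stop("degenerate circle fit")
  structure(list(
    center_y = unname(cy), center_z = unname(cz), radius = radius,
    rms_residual = sqrt(mean((d - radius)^2)), n_points = n
  ), class = "lsm_circlefit")
}

#' @export
print.lsm_circlefit <- function(x, ...) {
  cat(sprintf(paste0("Circle fit (%d points): centre (%.6g, %.6g) um, ",
                     "R = %.6g um, RMS residual %.3g um\n"),
              x$n_points, x$center_y, x$center_z, x$radius, x$rms_residual))
  cat(sprintf("  curvature: %.4g / mm\n", curvature_of(x)))
  invisible(x)
}

#' @export
coef.lsm_circlefit <- function(object, ...) {
  c(center_y = object$center_y, center_z = object$center_z,
    radius = object$radius)
}

#' Curvature of a fitted circle
#'
#' The reciprocal of the fitted radius, reported per millimetre: a 2.6 mm
#' radius corresponds to a curvature of 0.38/mm.
#'
#' @param fit An `"lsm_circlefit"`, or a radius in micrometres.
#' @return Curvature in 1/mm.
#' @examples
#' curvature_of(2600)  # R = 2.6 mm -> 0.3846.../mm
#' @export
curvature_of <- function(fit) {
  radius_um <- if (inherits(fit, "lsm_circlefit")) fit$radius else fit
  stopifnot(is.numeric(radius_um), radius_um > 0)
  1000 / radius_um
}
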