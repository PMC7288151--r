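#' An ordered scan of light-sheet frames
#'
#' Couples the frames of a line scan with the scan step (micrometres between
#' consecutive frames along the scan axis x), the lateral scale (micrometres
#' per image row along y), the calibration model used to turn pixel offsets
#' into heights, and the reference stripe column of the flat surface.
#'
#' @param frames List of [lsm_image()] frames in scan order (>= 2).
#' @param scan_step_um Scan step, micrometres (> 0).
#' @param lateral_scale_um Micrometres per image row (> 0).
#' @param calibration An `"lsm_calibration"`, or NULL to attach later.
#' @param reference_column Stripe column of the zero-height reference
#'   surface; if NULL it is derived from the first frame via
#'   [reference_column()] at reconstruction time.
#' @return An object of class `"scan_stack"`.
#' @export
scan_stack <- function(frames, scan_step_um, lateral_scale_um,
                       calibration = NULL, reference_column = NULL) {
  stopifnot(is.list(frames), length(frames) >= 2,
            scan_step_um > 0, lateral_scale_um > 0)
  if (!all(vapply(frames, inherits, logical(1), "lsm_image")))
    stop("frames must be a list of lsm_image objects")
  if (!is.null(calibration)) stopifnot(inherits(calibration, "lsm_calibration"))
  structure(list(
    frames = frames, scan_step_um = scan_step_um,
    lateral_scale_um = lateral_scale_um, calibration = calibration,
    reference_column = reference_column
  ), class = "scan_stack")
}

#' @export
print.scan_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("scan_stack: %d frames of %d x %d, scan step %g um, %g um/row\n",
              length(x$frames), d[1], d[2], x$scan_step_um, x$lateral_scale_um))
  cat(if (is.null(x$calibration)) "  no calibration attached\n"
      else sprintf("  calibration: degree %d, slope %g px/um\n",
                   x$calibration$degree, x$calibration$linear_slope))
  invisible(x)
}

#' Convert a scan stack into a 3D point cloud
#'
#' For every frame `k` and every valid contour row `i`, emits the point
#' `x = (k - 1) * scan_step`, `y = (i - 1) * lateral_scale`,
#' `z = invert_offset(calibration, stripe offset)`. The inversion is allowed
#' to extrapolate slightly beyond the calibrated range (`extend_um`, default
#' 5% of the range) so that noise around the zero-height reference inverts
#' symmetrically instead of being rectified at the range floor; offsets
#' beyond the extension are clamped. Invalid rows are omitted.
#'
#' @param stack A [scan_stack()] with a calibration attached.
#' @param reference_column Overrides the stack's reference column.
#' @param smooth Logical; smooth frames before contour extraction.
#' @param radius,eps Guided-filter parameters, see [smooth_image()].
#' @param extend_um Calibration extrapolation allowance, micrometres; see
#'   [invert_offset()].
#' @return A data frame with columns `x`, `y`, `z` (micrometres), `frame`,
#'   `row`, of class `"lsm_pointcloud"`.
#' @export
stack_to_pointcloud <- function(stack, reference_column = NULL, smooth = TRUE,
                                radius = 4, eps = NULL, extend_um = NULL) {
  stopifnot(inherits(stack, "scan_stack"))
  cal <- stack$calibration
  if (is.null(cal)) stop("scan stack has no calibration attached")
  contours <- lapply(stack$frames, function(fr) {
    if (smooth) fr <- smooth_image(fr, radius = radius, eps = eps)
    extract_contour(fr)
  })
  refcol <- reference_column %||% stack$reference_column %||%
    reference_column(contours[[1]])
  if (is.null(extend_um)) extend_um <- 0.05 * diff(cal$invertible_z_range)
  # attainable offset range after extension, for clamping noise excursions
  zr <- cal$invertible_z_range
  if (extend_um > 0) {
    dcf <- cal$coefficients[-1] * seq_len(length(cal$coefficients) - 1)
    if (all(polyval(dcf, seq(zr[1] - extend_um, zr[1], length.out = 64)) > 0))
      zr[1] <- zr[1] - extend_um
    if (all(polyval(dcf, seq(zr[2], zr[2] + extend_um, length.out = 64)) > 0))
      zr[2] <- zr[2] + extend_um
  }
  n_rng <- polyval(cal$coefficients, zr)
  pts <- lapply(seq_along(contours), function(k) {
    ct <- contours[[k]]
    ok <- ct$valid
    if (!any(ok)) return(NULL)
    dn <- ct$column_position[ok] - refcol
    dn <- pmin(pmax(dn, n_rng[1]), n_rng[2])
    data.frame(
      x = (k - 1) * stack$scan_step_um,
      y = (ct$row[ok] - 1) * stack$lateral_scale_um,
      z = invert_offset(cal, dn, extend_um = extend_um),
      frame = k, row = ct$row[ok]
    )
  })
  out <- do.call(rbind, pts)
  if (is.null(out) || nrow(out) == 0) stop("point cloud is empty")
  class(out) <- c("lsm_pointcloud", "data.frame")
  out
}

#' Interpolate a point cloud onto a regular heightmap grid
#'
#' Linear scattered-data interpolation (Delaunay triangulation with
#' barycentric interpolation, via \pkg{interp}) of `z` onto a regular `(x,
#' y)` grid. Cells outside the convex hull of the points are masked. Linear
#' interpolation reproduces the data at the data points and is exact for
#' planar surfaces.
#'
#' @param points An `"lsm_pointcloud"` or any data frame with `x`, `y`, `z`
#'   (micrometres); >= 3 non-collinear points.
#' @param x_spacing_um,y_spacing_um Grid spacings, micrometres.
#' @return An object of class `"lsm_heightmap"`: list with `z` (matrix,
#'   x along rows, y along columns, NA where masked), grid vectors `x`, `y`,
#'   the spacings, and `mask`.
#' @export
grid_surface <- function(points, x_spacing_um, y_spacing_um) {
  stopifnot(all(c("x", "y", "z") %in% names(points)),
            x_spacing_um > 0, y_spacing_um > 0)
  if (nrow(points) < 3) stop("need at least 3 points")
  rx <- range(points$x); ry <- range(points$y)
  if (diff(rx) == 0 || diff(ry) == 0)
    stop("degenerate point cloud: zero extent in x or y")
  xo <- seq(rx[1], rx[2], by = x_spacing_um)
  yo <- seq(ry[1], ry[2], by = y_spacing_um)
  g <- tryCatch(
    interp::interp(points$x, points$y, points$z, xo = xo, yo = yo,
                   method = "linear", duplicate = "mean"),
    error = function(e) stop("scattered interpolation failed (degenerate ",
                             "geometry?): ", conditionMessage(e))
  )
  z <- g$z
  structure(list(
    z = z, x = xo, y = yo,
    x_spacing_um = x_spacing_um, y_spacing_um = y_spacing_um,
    mask = !is.na(z)
  ), class = "lsm_heightmap")
}

#' @export
print.lsm_heightmap <- function(x, ...) {
  cat(sprintf("lsm_heightmap: %d x %d cells (%g x %g um), %.1f%% valid\n",
              length(x$x), length(x$y), x$x_spacing_um, x$y_spacing_um,
              100 * mean(x$mask)))
  zz <- x$z[x$mask]
  cat(sprintf("  z range: [%g, %g] um\n", min(zz), max(zz)))
  invisible(x)
}

#' @export
plot.lsm_heightmap <- function(x, ...) {
  graphics::image(x$x, x$y, x$z, xlab = "x (um)", ylab = "y (um)",
                  col = grDevices::hcl.colors(64, "viridis"),
                  useRaster = TRUE, ...)
  invisible(x)
}

heightmap_region <- function(surface, region) {
  stopifnot(length(region) == 4)
  ix <- surface$x >= region[1] & surface$x <= region[2]
  iy <- surface$y >= region[3] & surface$y <= region[4]
  vals <- surface$z[ix, iy]
  vals[!is.na(vals)]
}

#' Step height between two heightmap regions
#'
#' Difference between the summarized heights of two rectangular regions,
#' `summary(high) - summary(low)`.
#'
#' The default summary is a 10%-trimmed mean. Contour positions are
#' quantized to whole pixels (one pixel is ~3.4 um of height at a typical
#' 0.29 px/um slope), and the median of quantized heights snaps to the pixel
#' grid — a bias of up to half a quantum, which is 17% of a 10 um step. The
#' speckle-induced jitter acts as natural dither that a mean exploits, and
#' trimming keeps the robustness to occasional extraction outliers that a
#' median would give.
#'
#' @param surface An `"lsm_heightmap"`.
#' @param region_hi,region_lo Rectangles `c(x_min, x_max, y_min, y_max)` in
#'   micrometres; each must cover >= 10 valid cells.
#' @param summary `"trimmed_mean"` (default), `"median"` or `"mean"`.
#' @param trim Trim fraction for `"trimmed_mean"` (default 0.1).
#' @return Step height, micrometres (negative if `region_hi` is lower).
#' @export
measure_step_height <- function(surface, region_hi, region_lo,
                                summary = c("trimmed_mean", "median", "mean"),
                                trim = 0.1) {
  summary <- match.arg(summary)
  stopifnot(inherits(surface, "lsm_heightmap"))
  sfun <- switch(summary,
    trimmed_mean = function(x) mean(x, trim = trim),
    median = stats::median,
    mean = mean
  )
  hi <- heightmap_region(surface, region_hi)
  lo <- heightmap_region(surface, region_lo)
  if (length(hi) < 10 || length(lo) < 10)
    stop("each region must contain at least 10 valid heightmap cells")
  sfun(hi) - sfun(lo)
}

#' Groove depth from per-frame contour offsets
#'
#' Implements the groove (indenture) depth protocol: in every frame, find
#' the extremal signed stripe offset relative to the flat-surface reference
#' column within a row window containing the groove; average these per-frame
#' offsets over all frames; optionally round the average to the nearest
#' integer pixel (the convention of instrument reports, where averaged
#' offsets are quoted as whole pixels); convert the offset magnitude to
#' depth through the inverse calibration.
#'
#' @param contours List of `lsm_contour` objects, one per frame.
#' @param reference_column Stripe column of the surrounding flat surface.
#' @param calibration An `"lsm_calibration"`.
#' @param row_window `c(first, last)` image rows bracketing the groove;
#'   default all rows.
#' @param round_offset Round the averaged pixel offset to an integer before
#'   inversion (default TRUE).
#' @return Groove depth, micrometres (positive).
#' @export
measure_groove_depth <- function(contours, reference_column, calibration,
                                 row_window = NULL, round_offset = TRUE) {
  stopifnot(is.list(contours), length(contours) >= 1,
            inherits(calibration, "lsm_calibration"))
  per_frame <- vapply(contours, function(ct) {
    stopifnot(inherits(ct, "lsm_contour"))
    keep <- ct$valid
    if (!is.null(row_window))
      keep <- keep & ct$row >= row_window[1] & ct$row <= row_window[2]
    if (!any(keep)) return(NA_real_)
    off <- ct$column_position[keep] - reference_column
    off[which.max(abs(off))]
  }, numeric(1))
  per_frame <- per_frame[!is.na(per_frame)]
  if (length(per_frame) == 0)
    stop("no indenture detected in any frame")
  dn <- mean(per_frame)
  if (round_offset) dn <- round(dn)
  invert_offset(calibration, abs(dn))
}

#' Relative measurement error in percent
#'
#' `100 * |measured - reference| / reference`, the standard figure of merit
#' against a certified standard (shim thickness, stylus profilometer depth).
#'
#' @param measured_um Measured value.
#' @param reference_um Non-zero reference value, same units.
#' @return Relative error, percent.
#' @examples
#' relative_error(20.25, 20)   # 1.25
#' relative_error(10.80, 10)   # 8
#' @export
relative_error <- function(measured_um, reference_um) {
  if (any(reference_um == 0)) stop("reference must be non-zero")
  100 * abs(measured_um - reference_um) / reference_um
}

#' Write a point cloud as whitespace-separated XYZ
#'
#' @param points An `"lsm_pointcloud"` or data frame with `x`, `y`, `z`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pointcloud_xyz <- function(points, path) {
  utils::write.table(points[, c("x", "y", "z")], path,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a point cloud as ASCII PLY
#'
#' @param points An `"lsm_pointcloud"` or data frame with `x`, `y`, `z`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pointcloud_ply <- function(points, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    paste("element vertex", nrow(points)),
    "property float x", "property float y", "property float z",
    "end_header"
  ), con)
  utils::write.table(points[, c("x", "y", "z")], con,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a heightmap to TIFF and/or CSV
#'
#' The TIFF stores heights as 32-bit samples normalized to the map's height
#' range, with a JSON sidecar (`<tiff_path>.json`) recording the affine
#' scale (`z_um = z_offset_um + sample * z_scale_um`), grid spacings and
#' mask; masked cells are written as 0 and flagged in the sidecar's mask
#' summary. The CSV is long format with exact micrometre columns `x`, `y`,
#' `z` (empty `z` where masked).
#'
#' @param surface An `"lsm_heightmap"`.
#' @param tiff_path,csv_path Output paths; either may be NULL to skip.
#' @return Invisibly, the written paths.
#' @seealso [read_heightmap()]
#' @export
write_heightmap <- function(surface, tiff_path = NULL, csv_path = NULL) {
  stopifnot(inherits(surface, "lsm_heightmap"))
  if (!is.null(tiff_path)) {
    zz <- surface$z[surface$mask]
    z0 <- min(zz)
    zs <- max(zz) - z0
    if (zs == 0) zs <- 1
    z <- (surface$z - z0) / zs
    z[!surface$mask] <- 0
    # rows of a TIFF are the image's y direction
    tiff::writeTIFF(t(z), tiff_path, bits.per.sample = 32, reduce = FALSE)
    jsonlite::write_json(list(
      z_offset_um = z0, z_scale_um = zs,
      x_origin_um = surface$x[1], y_origin_um = surface$y[1],
      x_spacing_um = surface$x_spacing_um,
      y_spacing_um = surface$y_spacing_um,
      n_masked = sum(!surface$mask)
    ), paste0(tiff_path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    long <- expand.grid(x = surface$x, y = surface$y)
    long$z <- as.vector(surface$z)
    utils::write.csv(long, csv_path, row.names = FALSE)
  }
  invisible(c(tiff_path, csv_path))
}

#' Read a heightmap written by [write_heightmap()] (CSV form)
#'
#' @param csv_path Path to the long-format CSV.
#' @return An `"lsm_heightmap"`.
#' @export
read_heightmap <- function(csv_path) {
  long <- utils::read.csv(csv_path)
  xo <- sort(unique(long$x)); yo <- sort(unique(long$y))
  z <- matrix(NA_real_, length(xo), length(yo))
  z[cbind(match(long$x, xo), match(long$y, yo))] <- long$z
  structure(list(
    z = z, x = xo, y = yo,
    x_spacing_um = if (length(xo) > 1) xo[2] - xo[1] else 1,
    y_spacing_um = if (length(yo) > 1) yo[2] - yo[1] else 1,
    mask = !is.na(z)
  ), class = "lsm_heightmap")
}
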