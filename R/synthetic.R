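# Run `code` with a private RNG stream; global .Random.seed is untouched.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

frame_seed <- function(seed, frame_index) {
  (as.integer(seed) + 7919L * as.integer(frame_index)) %% 2147483647L
}

#' Specify a synthetic light-sheet scene
#'
#' Describes everything needed to render light-sheet frames of a parametric
#' ground-truth surface. Each rendered row carries a Gaussian stripe
#' cross-section whose centre column encodes the local surface height through
#' a linear height-to-pixel map (the forward calibration slope), corrupted by
#' multiplicative speckle; this is the forward model the extraction and
#' calibration stages invert.
#'
#' @param surface_fn Function `(x_um, y_um) -> z_um` giving ground-truth
#'   height; must be vectorized over `y_um`.
#' @param sheet_sigma Stripe half-width (Gaussian sigma) in columns. The
#'   default, 6 px, corresponds to a sheet thickness of roughly 50 um imaged
#'   at the default height-to-pixel slope.
#' @param peak_intensity Stripe crest amplitude above background, counts.
#' @param background Background level, counts.
#' @param speckle_contrast Multiplicative speckle contrast in `[0, 1)`; each
#'   pixel is scaled by `max(0, 1 + contrast * N(0,1))`.
#' @param pixels_per_um Forward calibration slope: stripe shift in columns
#'   per micrometre of height. Default 0.29 px/um, a typical value for this
#'   class of instrument.
#' @param reference_column Stripe column at zero height (1-based, fractional
#'   allowed).
#' @param lateral_scale_um Physical length per image row, micrometres.
#'   Default 5.58 um/px (896 px spanning 5 mm).
#' @param bit_depth Camera bit depth for quantization.
#' @param seed RNG seed making every rendered frame reproducible.
#' @return An object of class `"scene_spec"`.
#' @seealso [preset_scene()] for ready-made test scenes, [render_frame()],
#'   [render_calibration_stack()], [render_scan_stack()].
#' @export
scene_spec <- function(surface_fn,
                       sheet_sigma = 6,
                       peak_intensity = 3400,
                       background = 100,
                       speckle_contrast = 0.15,
                       pixels_per_um = 0.29,
                       reference_column = 128,
                       lateral_scale_um = 5.58,
                       bit_depth = 12,
                       seed = 1L) {
  stopifnot(is.function(surface_fn), sheet_sigma > 0,
            speckle_contrast >= 0, speckle_contrast < 1,
            peak_intensity > background, background >= 0,
            pixels_per_um > 0, lateral_scale_um > 0)
  structure(list(
    surface_fn = surface_fn, sheet_sigma = sheet_sigma,
    peak_intensity = peak_intensity, background = background,
    speckle_contrast = speckle_contrast, pixels_per_um = pixels_per_um,
    reference_column = reference_column,
    lateral_scale_um = lateral_scale_um, bit_depth = as.integer(bit_depth),
    seed = as.integer(seed)
  ), class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat("Synthetic light-sheet scene\n")
  cat(sprintf("  stripe: sigma %g px, peak %g + background %g counts (%d-bit)\n",
              x$sheet_sigma, x$peak_intensity, x$background, x$bit_depth))
  cat(sprintf("  speckle contrast %g, %g px/um, reference column %g\n",
              x$speckle_contrast, x$pixels_per_um, x$reference_column))
  cat(sprintf("  lateral scale %g um/row, seed %d\n", x$lateral_scale_um, x$seed))
  invisible(x)
}

#' Render one light-sheet frame of a scene
#'
#' For each image row `i` (at lateral position `y = (i - 1) *
#' lateral_scale_um`) the stripe centre column is `reference_column +
#' pixels_per_um * z(x, y)`, with `z` the ground-truth surface height at the
#' scan position `x_position_um`, optionally offset by `z_offset_um` (used
#' for calibration stacks). Intensities are `background + peak *
#' exp(-(j - centre)^2 / (2 sigma^2))`, multiplied by a clipped Gaussian
#' speckle field and quantized to the scene's bit depth. Rendering is
#' deterministic given the scene seed and `frame_index`.
#'
#' @param scene A [scene_spec()].
#' @param x_position_um Scan-axis position of this frame, micrometres.
#' @param image_shape `c(H, W)` in pixels; default `c(1280, 1936)`, a common
#'   sensor format (reduce for fast tests).
#' @param frame_index Ordinal of the frame (feeds the per-frame RNG stream).
#' @param z_offset_um Height added uniformly to the surface.
#' @return An [lsm_image()].
#' @export
render_frame <- function(scene, x_position_um = 0,
                         image_shape = c(1280, 1936), frame_index = 1L,
                         z_offset_um = 0) {
  stopifnot(inherits(scene, "scene_spec"), length(image_shape) == 2)
  H <- image_shape[1]; W <- image_shape[2]
  y <- (seq_len(H) - 1) * scene$lateral_scale_um
  z <- scene$surface_fn(x_position_um, y) + z_offset_um
  centre <- scene$reference_column + scene$pixels_per_um * z
  if (any(centre < 1 | centre > W))
    stop("stripe centre falls outside the image for some rows ",
         "(height out of range for this image width)")
  dev <- outer(centre, seq_len(W), function(c, j) j - c)
  m <- scene$background +
    scene$peak_intensity * exp(-dev^2 / (2 * scene$sheet_sigma^2))
  if (scene$speckle_contrast > 0) {
    speckle <- with_seed(frame_seed(scene$seed, frame_index),
                         matrix(stats::rnorm(H * W), H, W))
    m <- m * pmax(0, 1 + scene$speckle_contrast * speckle)
  }
  maxval <- 2^scene$bit_depth - 1
  m <- round(pmin(pmax(m, 0), maxval))
  lsm_image(m, bit_depth = scene$bit_depth, frame_index = frame_index,
            stage_position_um = x_position_um)
}

#' Render a calibration stack of a flat surface
#'
#' Renders `n_steps` frames of a flat surface raised in increments of
#' `step_um`, emulating the standard calibration protocol (301 frames at
#' 2.5 um by default, covering 0-750 um).
#'
#' @param scene A [scene_spec()]; its `surface_fn` is ignored and replaced by
#'   a flat surface.
#' @param n_steps Number of frames (>= 2).
#' @param step_um Height increment, micrometres.
#' @param image_shape `c(H, W)` per frame.
#' @return List of [lsm_image()] frames, frame `k` at height
#'   `(k - 1) * step_um`.
#' @export
render_calibration_stack <- function(scene, n_steps = 301, step_um = 2.5,
                                     image_shape = c(1280, 1936)) {
  stopifnot(n_steps >= 2, step_um > 0)
  scene$surface_fn <- function(x, y) rep(0, length(y))
  lapply(seq_len(n_steps), function(k) {
    render_frame(scene, x_position_um = 0, image_shape = image_shape,
                 frame_index = k, z_offset_um = (k - 1) * step_um)
  })
}

#' Render a scan stack of a scene
#'
#' Renders `n_frames` frames stepping the scan position by `step_um`,
#' packaged as a [scan_stack()] ready for reconstruction.
#'
#' @param scene A [scene_spec()].
#' @param n_frames Number of frames (>= 2).
#' @param step_um Scan step between frames, micrometres.
#' @param image_shape `c(H, W)` per frame.
#' @param calibration Optional `"lsm_calibration"` to attach.
#' @return A `scan_stack`.
#' @export
render_scan_stack <- function(scene, n_frames, step_um,
                              image_shape = c(1280, 1936),
                              calibration = NULL) {
  stopifnot(n_frames >= 2, step_um > 0)
  frames <- lapply(seq_len(n_frames), function(k) {
    render_frame(scene, x_position_um = (k - 1) * step_um,
                 image_shape = image_shape, frame_index = k)
  })
  scan_stack(frames, scan_step_um = step_um,
             lateral_scale_um = scene$lateral_scale_um,
             calibration = calibration,
             reference_column = scene$reference_column)
}

#' Ready-made synthetic test scenes
#'
#' Returns a fully parameterized [scene_spec()] with documented ground truth:
#' \describe{
#'   \item{`flat`}{Flat surface at height 0.}
#'   \item{`stair_10_20`}{Two shims of 10 and 20 um stacked in a stair:
#'     plateaus at 0, 10 and 30 um in thirds along the row (y) direction.}
#'   \item{`grooves_70`}{A 70 um plateau cut by three flat-bottomed grooves
#'     reaching down to 0 (depth 70 um), running along the scan direction.}
#'   \item{`cylinder_edge`}{A circular-arc cap of radius 2605 um and peak
#'     height 600 um, uniform along the scan direction.}
#'   \item{`hair_bump`}{A cylinder of diameter 140 um resting on the flat
#'     surface (peak height 140 um), the classic single-hair target.}
#' }
#' Plateau/groove breakpoints scale with `extent_y_um`, the lateral span of
#' the rendered frames, so presets work at reduced image sizes.
#'
#' @param name One of `"flat"`, `"stair_10_20"`, `"grooves_70"`,
#'   `"cylinder_edge"`, `"hair_bump"`.
#' @param extent_y_um Lateral (row-direction) span the scene is designed
#'   for; defaults to 1280 rows at the default 5.58 um/row.
#' @param ... Overrides passed on to [scene_spec()].
#' @return A `scene_spec` with an extra attribute `ground_truth` (named list
#'   of the programmed dimensions).
#' @export
preset_scene <- function(name = c("flat", "stair_10_20", "grooves_70",
                                  "cylinder_edge", "hair_bump"),
                         extent_y_um = 1280 * 5.58, ...) {
  name <- match.arg(name)
  gt <- list()
  fn <- switch(name,
    flat = function(x, y) rep(0, length(y)),
    stair_10_20 = {
      b1 <- extent_y_um / 3; b2 <- 2 * extent_y_um / 3
      gt <- list(plateaus_um = c(0, 10, 30), step_heights_um = c(10, 20),
                 breaks_y_um = c(b1, b2))
      function(x, y) ifelse(y < b1, 0, ifelse(y < b2, 10, 30))
    },
    grooves_70 = {
      cy <- extent_y_um * c(0.25, 0.5, 0.75)
      hw <- 90   # um: ~180 um wide gate lines, independent of image size
      gt <- list(depth_um = 70, groove_centers_y_um = cy,
                 groove_halfwidth_um = hw)
      function(x, y) {
        z <- rep(70, length(y))
        for (c0 in cy) z[abs(y - c0) <= hw] <- 0
        z
      }
    },
    cylinder_edge = {
      R <- 2605; h <- 600; y0 <- extent_y_um / 2
      gt <- list(radius_um = R, cap_height_um = h, center_y_um = y0)
      function(x, y) {
        s <- R^2 - (y - y0)^2
        pmax(0, ifelse(s > 0, sqrt(pmax(s, 0)) - (R - h), 0))
      }
    },
    hair_bump = {
      r <- 70; y0 <- extent_y_um / 2
      gt <- list(peak_height_um = 140, diameter_um = 140, center_y_um = y0)
      function(x, y) {
        s <- r^2 - (y - y0)^2
        ifelse(s > 0, r + sqrt(pmax(s, 0)), 0)
      }
    }
  )
  sc <- scene_spec(surface_fn = fn, ...)
  attr(sc, "ground_truth") <- gt
  attr(sc, "preset") <- name
  sc
}
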