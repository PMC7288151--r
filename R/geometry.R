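#' Optical geometry of a laser-triangulation light-sheet system
#'
#' Bundles the fixed optical parameters of the instrument: the illumination
#' and viewing angles, the camera tilt, the imaging-lens focal length and
#' object distance, and the camera pixel pitch. The image distance is derived
#' from the thin-lens equation \eqn{1/l + 1/d = 1/f}.
#'
#' All angles are accepted in degrees (the convention of the instrument
#' literature) and converted to radians internally. Focal length and object
#' distance are accepted in millimetres and stored in micrometres, so that
#' every length inside the package is in micrometres.
#'
#' @param alpha_deg Angle between the incident light sheet and the surface
#'   normal, degrees, in (0, 90).
#' @param beta_deg Angle between the scattered (viewing) direction and the
#'   surface normal, degrees, in (0, 90).
#' @param theta_deg Angle between the object-to-image axis and the camera
#'   plane, degrees, in (0, 90]. 90 is the orthogonal configuration.
#' @param focal_length_mm Focal length of the imaging lens, mm.
#' @param object_distance_mm Distance from the object point to the imaging
#'   lens, mm; must exceed the focal length so a real image forms.
#' @param pixel_size_um Physical pixel pitch of the camera, micrometres.
#'
#' @return An object of class `"optical_geometry"`: a list with the angles in
#'   degrees, `focal_length_um`, `object_distance_um`, the derived
#'   `image_distance_um`, and `pixel_size_um`.
#' @examples
#' g <- optical_geometry(45, 45, 90, focal_length_mm = 50,
#'                       object_distance_mm = 150, pixel_size_um = 5.86)
#' g$image_distance_um / 1000  # mm
#' @export
optical_geometry <- function(alpha_deg, beta_deg, theta_deg,
                             focal_length_mm, object_distance_mm,
                             pixel_size_um) {
  stopifnot(is.numeric(alpha_deg), is.numeric(beta_deg), is.numeric(theta_deg))
  if (alpha_deg <= 0 || alpha_deg >= 90)
    stop("alpha_deg must lie in (0, 90)")
  if (beta_deg <= 0 || beta_deg >= 90)
    stop("beta_deg must lie in (0, 90)")
  if (theta_deg <= 0 || theta_deg > 90)
    stop("theta_deg must lie in (0, 90]")
  if (pixel_size_um <= 0)
    stop("pixel_size_um must be positive")
  f <- focal_length_mm * 1000
  l <- object_distance_mm * 1000
  d <- image_distance(focal_length_mm, object_distance_mm) * 1000
  structure(list(
    alpha_deg = alpha_deg, beta_deg = beta_deg, theta_deg = theta_deg,
    focal_length_um = f, object_distance_um = l, image_distance_um = d,
    pixel_size_um = pixel_size_um
  ), class = "optical_geometry")
}

#' @export
print.optical_geometry <- function(x, ...) {
  cat("Laser-triangulation optical geometry\n")
  cat(sprintf("  alpha = %g deg, beta = %g deg, theta = %g deg\n",
              x$alpha_deg, x$beta_deg, x$theta_deg))
  cat(sprintf("  f = %g mm, l = %g mm, d = %g mm (thin lens)\n",
              x$focal_length_um / 1000, x$object_distance_um / 1000,
              x$image_distance_um / 1000))
  cat(sprintf("  pixel pitch = %g um\n", x$pixel_size_um))
  invisible(x)
}

#' Image distance from the thin-lens equation
#'
#' Solves \eqn{1/l + 1/d = 1/f} for the image distance \eqn{d = l f / (l - f)}.
#'
#' @param focal_length_mm Focal length, mm (> 0).
#' @param object_distance_mm Object distance, mm; must exceed the focal length.
#' @return Image distance in mm.
#' @examples
#' image_distance(50, 100)  # symmetric 2f-2f conjugates: 100
#' image_distance(50, 150)  # 75
#' @export
image_distance <- function(focal_length_mm, object_distance_mm) {
  f <- focal_length_mm
  l <- object_distance_mm
  if (f <= 0) stop("focal length must be positive")
  if (l <= f)
    stop("object distance must exceed the focal length (no real image)")
  l * f / (l - f)
}

#' Height offset from camera-plane displacement, general oblique geometry
#'
#' Maps a lateral displacement `delta_x_um` of the imaged stripe in the camera
#' plane to the height offset of the surface relative to the reference plane:
#' \deqn{\Delta z = \frac{\Delta x \sin\theta \cos\alpha \, (l - f)}
#'   {f \sin(\alpha+\beta) \pm \Delta x \sin(\alpha+\beta+\theta)(1 - f/l)}}
#' The sign in the denominator depends on whether the actual surface lies
#' above (convexity, `+`) or below (concavity, `-`) the reference plane; it is
#' an explicit argument because the displacement magnitude alone cannot
#' decide it.
#'
#' @param delta_x_um Displacement magnitude in the camera plane, micrometres
#'   (>= 0).
#' @param geom An [optical_geometry()] object.
#' @param surface_side `"above"` (convexity) or `"below"` (concavity).
#' @return Height offset magnitude, micrometres.
#' @seealso [delta_z_linear()] for the orthogonal configuration
#'   (`alpha = beta = 45`, `theta = 90`) in which this mapping is exactly
#'   linear.
#' @examples
#' g <- optical_geometry(30, 60, 75, 50, 150, 5.86)
#' delta_z_general(100, g, "above")
#' @export
delta_z_general <- function(delta_x_um, geom, surface_side = c("above", "below")) {
  surface_side <- match.arg(surface_side)
  stopifnot(inherits(geom, "optical_geometry"))
  if (any(delta_x_um < 0)) stop("delta_x_um must be non-negative")
  a <- geom$alpha_deg * pi / 180
  b <- geom$beta_deg * pi / 180
  th <- geom$theta_deg * pi / 180
  f <- geom$focal_length_um
  l <- geom$object_distance_um
  sgn <- if (surface_side == "above") 1 else -1
  den <- f * sin(a + b) + sgn * delta_x_um * sin(a + b + th) * (1 - f / l)
  if (any(den <= 0))
    stop("displacement outside the geometric validity range (denominator <= 0)")
  delta_x_um * sin(th) * cos(a) * (l - f) / den
}

#' Height offset from displacement, orthogonal configuration
#'
#' In the orthogonal configuration (`alpha = beta = 45` degrees, `theta = 90`
#' degrees) the correction term of the general mapping vanishes
#' (\eqn{\sin(\alpha+\beta+\theta) = \sin 180^\circ = 0}) and height becomes
#' strictly proportional to stripe displacement:
#' \deqn{\Delta z = \Delta x \frac{\cos 45^\circ}{\sin 90^\circ}
#'   \frac{l - f}{f} = \Delta x \frac{l - f}{\sqrt{2} f}.}
#' This linearity is what makes the orthogonal layout attractive: a single
#' scale factor calibrates the whole height range.
#'
#' A note on the constant: the linear slope is sometimes quoted as
#' \eqn{(l-f)/(2f)}, which is not the reduction of the oblique formula. At
#' 45 degree incidence a height change \eqn{\Delta z} displaces the
#' illuminated spot by \eqn{\sqrt{2}\,\Delta z} perpendicular to the viewing
#' axis (the spot shifts \eqn{\Delta z \tan 45^\circ} laterally while rising
#' \eqn{\Delta z}), giving the \eqn{\sqrt 2} denominator; this reduction is
#' verified against a thin-lens ray trace in the package tests. In practice
#' the slope is superseded by the empirical pixel-offset calibration
#' ([build_calibration()]), which absorbs the true optical magnification.
#'
#' @param delta_x_um Displacement in the camera plane, micrometres.
#' @param focal_length_mm Focal length, mm.
#' @param object_distance_mm Object distance, mm (> focal length).
#' @return Height offset, micrometres (same sign as `delta_x_um`).
#' @examples
#' delta_z_linear(10, 50, 150)  # slope (l-f)/(sqrt(2) f) = sqrt(2)
#' g <- optical_geometry(45, 45, 90, 50, 150, 5.86)
#' delta_z_general(10, g, "above")  # identical
#' @export
delta_z_linear <- function(delta_x_um, focal_length_mm, object_distance_mm) {
  f <- focal_length_mm
  l <- object_distance_mm
  if (f <= 0 || l <= f)
    stop("need object_distance_mm > focal_length_mm > 0")
  delta_x_um * (l - f) / (sqrt(2) * f)
}

#' Camera-plane displacement from a pixel offset
#'
#' Converts a stripe displacement counted in camera pixels into a physical
#' displacement in the camera plane: \eqn{\Delta x = \Delta n \times
#' \mathrm{pixel\ size}}.
#'
#' @param delta_n_pixel Pixel offset (may be fractional or negative).
#' @param pixel_size_um Pixel pitch, micrometres (> 0).
#' @return Displacement in micrometres.
#' @examples
#' delta_x_from_pixels(36, 5.0)   # 180
#' delta_x_from_pixels(21, 2.5)   # 52.5
#' @export
delta_x_from_pixels <- function(delta_n_pixel, pixel_size_um) {
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  delta_n_pixel * pixel_size_um
}
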