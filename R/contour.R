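#' Extract the light-sheet contour from a frame
#'
#' For every image row, locates the brightest column of the (ideally
#' smoothed) frame. When the row maximum is attained at several columns —
#' common at limited bit depth, where the stripe crest saturates the
#' quantization — the position is the arithmetic mean of all tied columns,
#' so positions may be fractional. Rows whose maximum falls below
#' `min_intensity` carry no stripe and are marked invalid.
#'
#' Columns are reported 1-based: a stripe in the first image column has
#' position 1.
#'
#' @param img An [lsm_image()], typically after [smooth_image()].
#' @param min_intensity Minimum row maximum (counts) for a row to count as
#'   containing the sheet; default 5% of the dynamic range.
#' @return An object of class `"lsm_contour"`: a data frame with columns
#'   `row`, `column_position` (NA where invalid) and `valid`, plus attributes
#'   `frame_index` and `width`.
#' @export
extract_contour <- function(img, min_intensity = NULL) {
  stopifnot(inherits(img, "lsm_image"))
  if (is.null(min_intensity)) min_intensity <- 0.05 * (2^img$bit_depth - 1)
  m <- img$intensities
  H <- nrow(m); W <- ncol(m)
  row_max <- m[cbind(seq_len(H), max.col(m, ties.method = "first"))]
  ties <- m == row_max            # row_max recycles down columns: H x W
  pos <- as.vector(ties %*% seq_len(W)) / rowSums(ties)
  valid <- row_max >= min_intensity
  if (!any(valid)) stop("no light sheet detected: every row is below min_intensity")
  pos[!valid] <- NA_real_
  structure(
    data.frame(row = seq_len(H), column_position = pos, valid = valid),
    frame_index = img$frame_index,
    width = W,
    class = c("lsm_contour", "data.frame")
  )
}

#' Signed pixel offsets of a contour against a reference column
#'
#' Subtracts a reference column from each valid row's stripe position. The
#' sign follows the triangulation convention: a rightward shift (positive
#' offset) corresponds to a convexity (surface above the reference plane), a
#' leftward shift (negative) to a concavity.
#'
#' @param profile An [extract_contour()] result.
#' @param reference_column Reference stripe column (fractional allowed),
#'   e.g. from a flat region or the first calibration frame.
#' @return Numeric vector of per-row offsets in pixels (NA for invalid rows).
#' @export
contour_offsets <- function(profile, reference_column) {
  stopifnot(inherits(profile, "lsm_contour"), is.numeric(reference_column),
            length(reference_column) == 1)
  profile$column_position - reference_column
}

#' Reference column of a contour
#'
#' Median stripe position over the valid rows of a contour, the default way
#' a reference column is derived from a designated reference frame (first
#' calibration frame or a flat region).
#'
#' @param profile An [extract_contour()] result.
#' @return Fractional column.
#' @export
reference_column <- function(profile) {
  stopifnot(inherits(profile, "lsm_contour"))
  stats::median(profile$column_position[profile$valid])
}

#' Full width at half maximum of an intensity peak
#'
#' Measures the FWHM of a 1-D intensity profile: the distance between the two
#' points where the profile crosses half of its peak amplitude above
#' baseline, with linear interpolation between samples. Used to estimate the
#' lateral (row-direction) resolution of the system from a line target.
#'
#' @param intensity Numeric vector with a single dominant peak.
#' @param position_scale Physical length per sample, e.g. micrometres per
#'   pixel; default 1 (result in samples).
#' @param baseline Background level subtracted before halving; default the
#'   minimum of `intensity`.
#' @return FWHM in units of `position_scale`.
#' @examples
#' x <- seq(-50, 50)
#' estimate_fwhm(exp(-x^2 / (2 * 10^2)))  # ~ 2 sqrt(2 log 2) * 10 = 23.55
#' @export
estimate_fwhm <- function(intensity, position_scale = 1, baseline = NULL) {
  stopifnot(is.numeric(intensity), length(intensity) >= 3, position_scale > 0)
  if (is.null(baseline)) baseline <- min(intensity)
  peak_idx <- which.max(intensity)
  peak <- intensity[peak_idx]
  if (peak <= baseline) stop("profile has no peak above baseline")
  half <- baseline + (peak - baseline) / 2
  cross <- function(idx_seq) {
    # first crossing below `half` walking away from the peak
    for (k in idx_seq) {
      if (intensity[k] < half) {
        # between k and the neighbour one step back toward the peak
        k2 <- k + if (k < peak_idx) 1L else -1L
        frac <- (half - intensity[k]) / (intensity[k2] - intensity[k])
        return(k + frac * (k2 - k))
      }
    }
    stop("no half-maximum crossing found on one side of the peak")
  }
  if (peak_idx <= 1 || peak_idx >= length(intensity))
    stop("peak lies on the profile boundary; no half-maximum crossing on one side")
  left <- cross(rev(seq_len(peak_idx - 1)))
  right <- cross(seq(peak_idx + 1, length(intensity)))
  (right - left) * position_scale
}

#' Write contours of a scan to CSV
#'
#' One row per (frame, image row): columns `frame`, `row`, `column_position`,
#' `valid`.
#'
#' @param contours A single `lsm_contour` or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_contours <- function(contours, path) {
  if (inherits(contours, "lsm_contour")) contours <- list(contours)
  tab <- do.call(rbind, lapply(contours, function(ct) {
    data.frame(frame = attr(ct, "frame_index"), row = ct$row,
               column_position = ct$column_position, valid = ct$valid)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read contours written by [write_contours()]
#'
#' @param path CSV path.
#' @return A list of `lsm_contour` objects, one per frame, in frame order.
#' @export
read_contours <- function(path) {
  tab <- utils::read.csv(path)
  lapply(split(tab, tab$frame), function(d) {
    structure(
      data.frame(row = d$row, column_position = d$column_position,
                 valid = d$valid),
      frame_index = d$frame[1],
      width = NA_integer_,
      class = c("lsm_contour", "data.frame")
    )
  })
}
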