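#' Light-sheet camera frame
#'
#' A single grayscale frame: a matrix of intensities (rows = image rows,
#' columns = image columns) together with the camera bit depth, the frame's
#' ordinal position in a scan, and optionally the stage position along the
#' scan axis.
#'
#' @param intensities Numeric matrix, H x W with W >= 2, values in
#'   `[0, 2^bit_depth - 1]`.
#' @param bit_depth Camera bit depth: 8, 12 or 16.
#' @param frame_index Ordinal of the frame in its scan (1-based).
#' @param stage_position_um Optional stage position along the scan axis,
#'   micrometres.
#' @return An object of class `"lsm_image"`.
#' @export
lsm_image <- function(intensities, bit_depth = 12, frame_index = 1L,
                      stage_position_um = NULL) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("intensities must be a numeric matrix")
  if (nrow(intensities) < 1 || ncol(intensities) < 2)
    stop("image must have at least 1 row and 2 columns")
  if (!bit_depth %in% c(8, 12, 16))
    stop("bit_depth must be 8, 12 or 16")
  maxval <- 2^bit_depth - 1
  if (min(intensities) < 0 || max(intensities) > maxval)
    stop("intensities must lie in [0, 2^bit_depth - 1]")
  structure(list(
    intensities = intensities,
    bit_depth = as.integer(bit_depth),
    frame_index = as.integer(frame_index),
    stage_position_um = stage_position_um
  ), class = "lsm_image")
}

#' @export
print.lsm_image <- function(x, ...) {
  cat(sprintf("lsm_image: %d x %d, %d-bit, frame %d%s\n",
              nrow(x$intensities), ncol(x$intensities), x$bit_depth,
              x$frame_index,
              if (is.null(x$stage_position_um)) ""
              else sprintf(", stage %g um", x$stage_position_um)))
  invisible(x)
}

#' @export
dim.lsm_image <- function(x) dim(x$intensities)

#' Read a grayscale frame from TIFF or PNG
#'
#' Reads a single image file and returns it as an [lsm_image()]. Multi-channel
#' images are collapsed to grayscale by averaging channels. Pixel values are
#' rescaled from the file's `[0, 1]` convention to integer counts at the
#' requested bit depth.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param bit_depth Bit depth to interpret counts at (default 16).
#' @param frame_index,stage_position_um Passed to [lsm_image()].
#' @return An `lsm_image`.
#' @export
read_frame <- function(path, bit_depth = 16, frame_index = 1L,
                       stage_position_um = NULL) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: ", ext)
  )
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
  counts <- round(img * (2^bit_depth - 1))
  lsm_image(counts, bit_depth = bit_depth, frame_index = frame_index,
            stage_position_um = stage_position_um)
}

#' Write a frame to TIFF or PNG
#'
#' Counts are scaled to the `[0, 1]` range of the file format using the
#' frame's bit depth and written as 16-bit samples.
#'
#' @param img An [lsm_image()].
#' @param path Output path ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_frame <- function(img, path) {
  stopifnot(inherits(img, "lsm_image"))
  scaled <- img$intensities / (2^img$bit_depth - 1)
  scaled[scaled < 0] <- 0
  scaled[scaled > 1] <- 1
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(scaled, path, bits.per.sample = 16),
    png = png::writePNG(scaled, path),
    stop("unsupported image format: ", ext)
  )
  invisible(path)
}

#' Read an ordered stack of frames from a directory
#'
#' Frame order is taken from a `manifest.csv` (columns `file`,
#' `stage_position_um`) when one is present in the directory, otherwise from
#' the lexicographic order of the image file names.
#'
#' @param dir Directory containing `.tif`/`.tiff`/`.png` frames.
#' @param bit_depth Bit depth to interpret counts at.
#' @return List of `lsm_image` objects in scan order.
#' @export
read_frame_stack <- function(dir, bit_depth = 16) {
  manifest <- file.path(dir, "manifest.csv")
  if (file.exists(manifest)) {
    mf <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    files <- file.path(dir, mf$file)
    pos <- if ("stage_position_um" %in% names(mf)) mf$stage_position_um
           else rep(list(NULL), nrow(mf))
  } else {
    files <- sort(list.files(dir, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    pos <- rep(list(NULL), length(files))
  }
  if (length(files) == 0) stop("no frames found in ", dir)
  lapply(seq_along(files), function(k) {
    sp <- if (is.list(pos)) pos[[k]] else pos[k]
    read_frame(files[k], bit_depth = bit_depth, frame_index = k,
               stage_position_um = sp)
  })
}
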