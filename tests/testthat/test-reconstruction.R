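make_stack <- function(name, seed, n_frames = 8, step = 10,
                       shape = tiny_shape, contrast = 0.15) {
  sc <- tiny_scene(name, seed = seed, H = shape[1],
                   speckle_contrast = contrast)
  cal <- linear_truth_calibration()
  list(scene = sc,
       stack = render_scan_stack(sc, n_frames = n_frames, step_um = step,
                                 image_shape = shape, calibration = cal))
}

test_that("a flat scene reconstructs to heights at the noise floor", {
  ms <- make_stack("flat", seed = 31)
  pc <- stack_to_pointcloud(ms$stack)
  expect_lt(abs(median(pc$z)), 2)     # um; below the pixel quantum 1/0.29
  expect_lt(unname(quantile(abs(pc$z), 0.99)), 12)  # ~3.5 pixel quanta
  expect_lt(max(abs(pc$z)), 20)
})

test_that("point count equals the number of valid contour rows", {
  ms <- make_stack("flat", seed = 32, n_frames = 5)
  pc <- stack_to_pointcloud(ms$stack)
  n_valid <- sum(vapply(ms$stack$frames, function(fr)
    sum(extract_contour(smooth_image(fr))$valid), numeric(1)))
  expect_identical(nrow(pc), as.integer(n_valid))
})

test_that("point-cloud coordinates span the programmed scan extents", {
  ms <- make_stack("flat", seed = 33, n_frames = 6, step = 12)
  pc <- stack_to_pointcloud(ms$stack)
  expect_equal(diff(range(pc$x)), (6 - 1) * 12)
  expect_equal(diff(range(pc$y)), (tiny_shape[1] - 1) * 5.58)
})

test_that("a stair scene reconstructs to its programmed plateaus", {
  ms <- make_stack("stair_10_20", seed = 34, n_frames = 10)
  pc <- stack_to_pointcloud(ms$stack)
  gt <- attr(ms$scene, "ground_truth")
  b <- gt$breaks_y_um
  margin <- 40  # um clearance from the step transitions
  est <- function(zz) mean(zz, trim = 0.1)  # speckle dithers the quantization
  z_lo <- est(pc$z[pc$y < b[1] - margin])
  z_mid <- est(pc$z[pc$y > b[1] + margin & pc$y < b[2] - margin])
  z_hi <- est(pc$z[pc$y > b[2] + margin])
  expect_lt(abs(z_lo - 0), 2.5)
  expect_lt(abs(z_mid - 10) / 10, 0.08)
  expect_lt(abs(z_hi - 30) / 30, 0.08)
})

test_that("gridding reproduces on-grid data and is exact on planes", {
  # points already on the grid
  pts <- expand.grid(x = seq(0, 40, 10), y = seq(0, 30, 10))
  pts$z <- 3 + 0.1 * pts$x
  hm <- grid_surface(pts, 10, 10)
  expect_equal(hm$z[, 1], 3 + 0.1 * hm$x, tolerance = 1e-12)
  # plane z = a x + b y + c sampled irregularly
  set.seed(35)
  sp <- data.frame(x = runif(200, 0, 100), y = runif(200, 0, 80))
  sp$z <- 0.3 * sp$x - 0.2 * sp$y + 5
  hm2 <- grid_surface(sp, 5, 5)
  want <- outer(hm2$x, hm2$y, function(x, y) 0.3 * x - 0.2 * y + 5)
  expect_equal(hm2$z[hm2$mask], want[hm2$mask], tolerance = 1e-9)
  expect_gt(sum(hm2$mask), 0.5 * length(hm2$mask))
})

test_that("grid cells outside the convex hull are masked", {
  # diamond-shaped cloud: bounding-box corners lie outside the hull
  pts <- data.frame(x = c(50, 100, 50, 0), y = c(0, 50, 100, 50))
  pts$z <- 1
  hm <- grid_surface(pts, 10, 10)
  expect_false(hm$mask[1, 1])                  # corner
  expect_true(hm$mask[6, 6])                   # centre
  expect_true(all(is.na(hm$z[!hm$mask])))
})

test_that("grid_surface rejects degenerate geometry", {
  expect_error(grid_surface(data.frame(x = 1:2, y = 1:2, z = 1:2), 1, 1),
               "at least 3")
  expect_error(grid_surface(data.frame(x = c(1, 2, 3), y = c(5, 5, 5),
                                       z = 1:3), 1, 1), "degenerate")
})

test_that("step height is the summarized difference between two regions", {
  ms <- make_stack("stair_10_20", seed = 36, n_frames = 10)
  pc <- stack_to_pointcloud(ms$stack)
  hm <- grid_surface(pc, 10, 5.58)
  gt <- attr(ms$scene, "ground_truth")
  b <- gt$breaks_y_um
  m <- 40
  xr <- range(pc$x)
  r_lo <- c(xr, 0, b[1] - m)
  r_mid <- c(xr, b[1] + m, b[2] - m)
  r_hi <- c(xr, b[2] + m, max(pc$y))
  s1 <- measure_step_height(hm, r_mid, r_lo)
  s2 <- measure_step_height(hm, r_hi, r_mid)
  expect_lt(relative_error(s1, 10), 8)
  expect_lt(relative_error(s2, 20), 8)
  # identical regions give zero; swapping regions negates
  expect_equal(measure_step_height(hm, r_lo, r_lo), 0)
  expect_equal(measure_step_height(hm, r_lo, r_mid), -s1)
  expect_error(measure_step_height(hm, c(0, 1, 0, 1), r_lo), "at least 10")
})

test_that("groove depth averages per-frame indenture offsets and inverts", {
  cal <- printed_calibration()
  mk_contour <- function(dn, frame) {
    structure(data.frame(row = 1:50,
                         column_position = c(rep(500, 20),
                                             rep(500 - dn, 10),
                                             rep(500, 20)),
                         valid = TRUE),
              frame_index = frame, width = 600,
              class = c("lsm_contour", "data.frame"))
  }
  # all frames at offset 21 -> depth is the root of the printed polynomial
  cts <- lapply(1:5, function(k) mk_contour(21, k))
  expect_equal(measure_groove_depth(cts, 500, cal), 74.753203,
               tolerance = 1e-4)
  # offsets 20, 21, 22 average to 21 -> same depth
  cts2 <- lapply(1:3, function(k) mk_contour(19 + k, k))
  expect_equal(measure_groove_depth(cts2, 500, cal), 74.753203,
               tolerance = 1e-4)
  # without rounding, a fractional mean offset is inverted as-is
  cts3 <- lapply(1:2, function(k) mk_contour(20 + k, k))
  d3 <- measure_groove_depth(cts3, 500, cal, round_offset = FALSE)
  expect_equal(predict_offset(cal, d3), 21.5, tolerance = 1e-5)
  # no valid rows anywhere -> no indenture
  empty <- lapply(cts, function(ct) { ct$valid <- FALSE; ct })
  expect_error(measure_groove_depth(empty, 500, cal), "no indenture")
})

test_that("synthetic grooves are recovered to their programmed depth", {
  sc <- tiny_scene("grooves_70", seed = 37, H = 192)
  cal <- linear_truth_calibration()
  stack <- render_scan_stack(sc, n_frames = 6, step_um = 50,
                             image_shape = c(192, 160), calibration = cal)
  contours <- lapply(stack$frames, function(fr)
    extract_contour(smooth_image(fr)))
  # reference = the 70 um plateau's stripe column; indenture dips below it
  ref <- stats::median(vapply(contours, reference_column, numeric(1)))
  depth <- measure_groove_depth(contours, ref, cal)
  expect_lt(relative_error(depth, 70), 5)
})

test_that("relative error is |measured - reference| / reference in percent", {
  expect_equal(relative_error(20.25, 20), 1.25)
  expect_equal(relative_error(10.80, 10), 8.00)
  expect_equal(round(relative_error(72, 74.5), 1), 3.4)
  expect_equal(round(relative_error(71, 74.5), 1), 4.7)
  expect_error(relative_error(10, 0), "non-zero")
})

test_that("stairs, grooves and bumps are recovered across seeds", {
  for (seed in 1:10) {
    cal <- linear_truth_calibration()
    # stair: both step heights within 8%. Smoothing correlates neighbouring
    # rows (shared filter windows), so frames — which carry independent
    # speckle — are the axis that buys averaging; regions need enough of
    # them for the dithered average to beat the pixel quantum.
    ms <- make_stack("stair_10_20", seed = 200 + seed, n_frames = 20,
                     shape = c(160, 160))
    pc <- stack_to_pointcloud(ms$stack)
    b <- attr(ms$scene, "ground_truth")$breaks_y_um
    est <- function(zz) mean(zz, trim = 0.1)
    z1 <- est(pc$z[pc$y < b[1] - 40])
    z2 <- est(pc$z[pc$y > b[1] + 40 & pc$y < b[2] - 40])
    z3 <- est(pc$z[pc$y > b[2] + 40])
    expect_lt(relative_error(z2 - z1, 10), 8)
    expect_lt(relative_error(z3 - z2, 20), 8)
    # bump: peak height within 8%
    sc <- tiny_scene("hair_bump", seed = 300 + seed, H = 96)
    stk <- render_scan_stack(sc, n_frames = 4, step_um = 10,
                             image_shape = c(96, 160), calibration = cal)
    pcb <- stack_to_pointcloud(stk)
    peak <- median(tapply(pcb$z, pcb$frame, max))  # robust to single-row spikes
    expect_lt(relative_error(peak, 140), 8)
  }
})

test_that("point clouds and heightmaps round-trip through their file formats", {
  ms <- make_stack("flat", seed = 38, n_frames = 4, shape = c(24, 120))
  pc <- stack_to_pointcloud(ms$stack)
  hm <- grid_surface(pc, 10, 5.58)
  xyz <- withr::local_tempfile(fileext = ".xyz")
  ply <- withr::local_tempfile(fileext = ".ply")
  tif <- withr::local_tempfile(fileext = ".tif")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_pointcloud_xyz(pc, xyz)
  back <- utils::read.table(xyz, col.names = c("x", "y", "z"))
  expect_equal(back$z, pc$z, tolerance = 1e-6)
  write_pointcloud_ply(pc, ply)
  hdr <- readLines(ply, n = 7)
  expect_identical(hdr[1], "ply")
  expect_identical(hdr[3], paste("element vertex", nrow(pc)))
  write_heightmap(hm, tiff_path = tif, csv_path = csv)
  hm2 <- read_heightmap(csv)
  expect_equal(hm2$z, hm$z)
  expect_identical(hm2$mask, hm$mask)
  # TIFF carries the normalized surface plus an affine sidecar in um
  side <- jsonlite::read_json(paste0(tif, ".json"), simplifyVector = TRUE)
  z_tiff <- t(tiff::readTIFF(tif)) * side$z_scale_um + side$z_offset_um
  expect_equal(z_tiff[hm$mask], hm$z[hm$mask], tolerance = 1e-4)
})
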