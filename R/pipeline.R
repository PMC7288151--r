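#' Read a run configuration file
#'
#' Configurations are flat key-value YAML files; keys mirror the arguments
#' of [run_pipeline()] (e.g. `scene`, `n_frames`, `scan_step_um`, `degree`,
#' `lateral_scale_um`, `calibration_path`, `input_dir`, `output_dir`,
#' `seed`). CLI flags override file values.
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a flat key-value mapping")
  cfg
}

pipeline_log <- function(out_dir, command, config) {
  jsonlite::write_json(list(
    command = command,
    config = config,
    package = "lsmtopo",
    version = as.character(utils::packageVersion("lsmtopo")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), file.path(out_dir, paste0(command, "-log.json")),
  auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE)
}

cfg_get <- function(config, key, default = NULL, required = FALSE) {
  val <- config[[key]]
  if (is.null(val)) {
    if (required) stop("missing required config key: ", key)
    return(default)
  }
  val
}

#' Run a pipeline command
#'
#' Orchestrates the end-to-end workflow from a configuration list: rendering
#' synthetic scans, calibrating from a frame directory, extracting contours,
#' reconstructing heightmaps, and the three metrology commands. Every run
#' echoes its configuration, package version and seed into a provenance log
#' in the output directory, and outputs are deterministic for a fixed seed.
#' On error, files created by the failed run are removed.
#'
#' @param command One of `"simulate"`, `"calibrate"`, `"extract"`,
#'   `"reconstruct"`, `"measure-step"`, `"measure-groove"`,
#'   `"measure-curvature"`.
#' @param config Named list (see [read_run_config()]) with the keys the
#'   command needs; `output_dir` is required for all commands.
#' @return A named list of results / written artifact paths, invisibly for
#'   file-producing commands.
#' @export
run_pipeline <- function(command, config) {
  commands <- c("simulate", "calibrate", "extract", "reconstruct",
                "measure-step", "measure-groove", "measure-curvature")
  if (length(command) != 1 || !command %in% commands)
    stop("unknown command: ", paste(command, collapse = " "),
         " (expected one of: ", paste(commands, collapse = ", "), ")")
  out_dir <- cfg_get(config, "output_dir", required = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pre_existing <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  result <- tryCatch(
    switch(command,
      "simulate" = pipeline_simulate(config, out_dir),
      "calibrate" = pipeline_calibrate(config, out_dir),
      "extract" = pipeline_extract(config, out_dir),
      "reconstruct" = pipeline_reconstruct(config, out_dir),
      "measure-step" = pipeline_measure_step(config, out_dir),
      "measure-groove" = pipeline_measure_groove(config, out_dir),
      "measure-curvature" = pipeline_measure_curvature(config, out_dir)
    ),
    error = function(e) {
      made <- setdiff(list.files(out_dir, recursive = TRUE, full.names = TRUE),
                      pre_existing)
      unlink(made)
      stop(e)
    }
  )
  pipeline_log(out_dir, command, config)
  invisible(result)
}

pipeline_scene <- function(config) {
  name <- cfg_get(config, "scene", "flat")
  h <- cfg_get(config, "image_height", 1280)
  preset_scene(
    name,
    extent_y_um = h * cfg_get(config, "lateral_scale_um", 5.58),
    lateral_scale_um = cfg_get(config, "lateral_scale_um", 5.58),
    speckle_contrast = cfg_get(config, "speckle_contrast", 0.15),
    pixels_per_um = cfg_get(config, "pixels_per_um", 0.29),
    reference_column = cfg_get(config, "reference_column", 128),
    sheet_sigma = cfg_get(config, "sheet_sigma", 6),
    seed = cfg_get(config, "seed", 1L)
  )
}

pipeline_shape <- function(config) {
  c(cfg_get(config, "image_height", 1280), cfg_get(config, "image_width", 1936))
}

pipeline_simulate <- function(config, out_dir) {
  scene <- pipeline_scene(config)
  shape <- pipeline_shape(config)
  n <- cfg_get(config, "n_frames", required = TRUE)
  step <- cfg_get(config, "scan_step_um", required = TRUE)
  files <- character(n)
  positions <- (seq_len(n) - 1) * step
  for (k in seq_len(n)) {
    fr <- render_frame(scene, x_position_um = positions[k],
                       image_shape = shape, frame_index = k)
    files[k] <- sprintf("frame_%04d.tif", k)
    write_frame(fr, file.path(out_dir, files[k]))
  }
  utils::write.csv(data.frame(file = files, stage_position_um = positions),
                   file.path(out_dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(list(
    scene = attr(scene, "preset"), ground_truth = attr(scene, "ground_truth"),
    n_frames = n, scan_step_um = step,
    lateral_scale_um = scene$lateral_scale_um,
    pixels_per_um = scene$pixels_per_um,
    reference_column = scene$reference_column, seed = scene$seed
  ), file.path(out_dir, "ground_truth.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(frames = file.path(out_dir, files),
       manifest = file.path(out_dir, "manifest.csv"))
}

pipeline_calibrate <- function(config, out_dir) {
  step <- cfg_get(config, "step_um", required = TRUE)
  degree <- cfg_get(config, "degree", 5)
  input_dir <- cfg_get(config, "input_dir")
  frames <- if (!is.null(input_dir)) {
    read_frame_stack(input_dir, bit_depth = cfg_get(config, "bit_depth", 16))
  } else {
    # no frame directory: render the calibration stack synthetically
    render_calibration_stack(pipeline_scene(config),
                             n_steps = cfg_get(config, "n_steps", 301),
                             step_um = step,
                             image_shape = pipeline_shape(config))
  }
  model <- calibrate_stack(frames, step_um = step, degree = degree,
                           summary = cfg_get(config, "summary", "median"))
  path <- file.path(out_dir, "calibration.json")
  write_calibration(model, path,
                    metadata = list(step_um = step, n_frames = length(frames)))
  list(model = model, path = path)
}

pipeline_extract <- function(config, out_dir) {
  input_dir <- cfg_get(config, "input_dir", required = TRUE)
  frames <- read_frame_stack(input_dir,
                             bit_depth = cfg_get(config, "bit_depth", 16))
  contours <- lapply(frames, function(fr) extract_contour(smooth_image(fr)))
  path <- file.path(out_dir, "contours.csv")
  write_contours(contours, path)
  list(contours = contours, path = path)
}

pipeline_reconstruct <- function(config, out_dir) {
  input_dir <- cfg_get(config, "input_dir", required = TRUE)
  cal <- read_calibration(cfg_get(config, "calibration_path", required = TRUE))
  frames <- read_frame_stack(input_dir,
                             bit_depth = cfg_get(config, "bit_depth", 16))
  stack <- scan_stack(
    frames,
    scan_step_um = cfg_get(config, "scan_step_um", required = TRUE),
    lateral_scale_um = cfg_get(config, "lateral_scale_um", required = TRUE),
    calibration = cal,
    reference_column = cfg_get(config, "reference_column")
  )
  pts <- stack_to_pointcloud(stack)
  surface <- grid_surface(
    pts,
    x_spacing_um = cfg_get(config, "x_spacing_um", stack$scan_step_um),
    y_spacing_um = cfg_get(config, "y_spacing_um", stack$lateral_scale_um)
  )
  write_pointcloud_xyz(pts, file.path(out_dir, "pointcloud.xyz"))
  write_pointcloud_ply(pts, file.path(out_dir, "pointcloud.ply"))
  write_heightmap(surface, tiff_path = file.path(out_dir, "heightmap.tif"),
                  csv_path = file.path(out_dir, "heightmap.csv"))
  list(pointcloud = pts, surface = surface)
}

pipeline_measure_step <- function(config, out_dir) {
  surface <- read_heightmap(cfg_get(config, "heightmap_path", required = TRUE))
  res <- list(step_height_um = measure_step_height(
    surface,
    region_hi = as.numeric(cfg_get(config, "region_hi", required = TRUE)),
    region_lo = as.numeric(cfg_get(config, "region_lo", required = TRUE)),
    summary = cfg_get(config, "summary", "trimmed_mean")
  ))
  jsonlite::write_json(res, file.path(out_dir, "step_height.json"),
                       auto_unbox = TRUE, digits = NA)
  res
}

pipeline_measure_groove <- function(config, out_dir) {
  contours <- read_contours(cfg_get(config, "contours_path", required = TRUE))
  cal <- read_calibration(cfg_get(config, "calibration_path", required = TRUE))
  rw <- cfg_get(config, "row_window")
  res <- list(groove_depth_um = measure_groove_depth(
    contours,
    reference_column = cfg_get(config, "reference_column", required = TRUE),
    calibration = cal,
    row_window = if (!is.null(rw)) as.numeric(rw),
    round_offset = cfg_get(config, "round_offset", TRUE)
  ))
  jsonlite::write_json(res, file.path(out_dir, "groove_depth.json"),
                       auto_unbox = TRUE, digits = NA)
  res
}

pipeline_measure_curvature <- function(config, out_dir) {
  contours <- read_contours(cfg_get(config, "contours_path", required = TRUE))
  frame <- cfg_get(config, "frame", 1)
  cal <- read_calibration(cfg_get(config, "calibration_path", required = TRUE))
  arc <- select_arc(
    contours[[frame]],
    row_range = as.numeric(cfg_get(config, "row_range", required = TRUE)),
    lateral_scale_um = cfg_get(config, "lateral_scale_um", required = TRUE),
    calibration = cal,
    reference_column = cfg_get(config, "reference_column")
  )
  fit <- fit_circle(arc)
  res <- list(center_y_um = fit$center_y, center_z_um = fit$center_z,
              radius_um = fit$radius,
              curvature_per_mm = curvature_of(fit),
              rms_um = fit$rms_residual, n_points = fit$n_points)
  jsonlite::write_json(res, file.path(out_dir, "curvature.json"),
                       auto_unbox = TRUE, digits = NA)
  res
}
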