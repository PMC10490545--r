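#' Run configuration for the reconstruction pipeline
#'
#' A single plain-list configuration drives all pipeline stages
#' (simulate, calibrate, reconstruct, metrics) and round-trips losslessly
#' through YAML.  Fields: `paths` (dataset root; keypoint dirs, corner
#' CSVs and outputs live beneath it), `sync_offset` (integer frames
#' applied to camera 2), `c_min` (confidence gate), `seed`, and the
#' synthetic-scene parameters (`rig`, `noise`, `duration_s`, `n_views`,
#' `corner_noise_sd`, `subject`).
#'
#' @param root Dataset root directory.
#' @param ... Overrides of any default field.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(root, ...) {
  cfg <- list(
    root = root,
    sync_offset = 0L,
    c_min = 0.1,
    seed = 1L,
    subject = 1L,
    duration_s = 25,
    n_views = 15,
    corner_noise_sd = 0,
    sigma_px = 0,
    dropout = 0,
    yaw_deg = 25,
    pitch_deg = 30,
    baseline_mm = 2000,
    frame_rate = 30,
    world_rotation = as.numeric(diag(3)))
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) stop(sprintf("unknown config field '%s'", nm))
    cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "run_config")
}

config_paths <- function(cfg) {
  list(keypoints1 = file.path(cfg$root, "keypoints_cam1"),
       keypoints2 = file.path(cfg$root, "keypoints_cam2"),
       corners1 = file.path(cfg$root, "corners_cam1.csv"),
       corners2 = file.path(cfg$root, "corners_cam2.csv"),
       truth = file.path(cfg$root, "ground_truth.csv"),
       calibration = file.path(cfg$root, "calibration.yaml"),
       error_audit = file.path(cfg$root, "calibration_errors.csv"),
       skeleton = file.path(cfg$root, "skeleton.csv"),
       lengths = file.path(cfg$root, "segment_lengths.csv"),
       length_series = file.path(cfg$root, "length_series.csv"),
       angles = file.path(cfg$root, "angle_series.csv"),
       config = file.path(cfg$root, "run_config.yaml"))
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @param file YAML path.
#' @export
write_run_config <- function(cfg, file) {
  yaml::write_yaml(unclass(cfg), file, precision = 15)
  invisible(file)
}

#' @rdname run_config
#' @export
read_run_config <- function(file) {
  x <- yaml::read_yaml(file)
  do.call(run_config, c(list(root = x$root),
                        x[setdiff(names(x), "root")]))
}

config_rig <- function(cfg) {
  virtual_rig(yaw_deg = cfg$yaw_deg, pitch_deg = cfg$pitch_deg,
              baseline_mm = cfg$baseline_mm, frame_rate = cfg$frame_rate)
}

#' Pipeline stage: generate a synthetic dataset on disk
#'
#' Builds the default rider mannequin, interpolates it through the
#' subject's posture schedule, renders it through the configured rig with
#' the configured noise, and writes everything the downstream stages
#' need: two per-frame keypoint JSON directories, paired checkerboard
#' corner CSVs, a ground-truth skeleton CSV, and the config itself.
#'
#' @param cfg A `run_config`.
#' @return Invisibly, the `config_paths()` list.
#' @export
pipeline_simulate <- function(cfg) {
  dir.create(cfg$root, recursive = TRUE, showWarnings = FALSE)
  p <- config_paths(cfg)
  rig <- config_rig(cfg)
  spec <- mannequin_spec()
  keyframes <- default_rider_keyframes(
    spec, schedule = default_posture_schedule(cfg$subject))
  traj <- build_motion(keyframes, spec, frame_rate = cfg$frame_rate,
                       duration = cfg$duration_s)
  rendered <- render_keypoint_series(
    traj, rig, noise_model(sigma_px = cfg$sigma_px, dropout = cfg$dropout,
                           seed = cfg$seed))
  write_openpose_json(rendered$series1, p$keypoints1, 1)
  write_openpose_json(rendered$series2, p$keypoints2, 2)
  boards <- render_checkerboard_views(checkerboard_spec(), rig,
                                      n_views = cfg$n_views,
                                      noise_sd = cfg$corner_noise_sd,
                                      seed = cfg$seed + 1L)
  write_corner_views(boards$views, p$corners1, p$corners2)
  truth <- traj$points
  utils::write.csv(data.frame(
    frame = rep(seq_len(dim(truth)[3]) - 1L, each = N_KEYPOINTS),
    keypoint_index = rep(0:(N_KEYPOINTS - 1L), times = dim(truth)[3]),
    x_mm = as.numeric(truth[, 1, ]), y_mm = as.numeric(truth[, 2, ]),
    z_mm = as.numeric(truth[, 3, ])), p$truth, row.names = FALSE)
  write_run_config(cfg, p$config)
  invisible(p)
}

#' Pipeline stage: calibrate the stereo rig from corner CSVs
#'
#' @param cfg A `run_config` whose root holds the corner CSVs.
#' @return The `stereo_calibration`, invisibly; writes the calibration
#'   YAML and the per-view reprojection-error audit CSV.
#' @export
pipeline_calibrate <- function(cfg) {
  p <- config_paths(cfg)
  views <- read_corner_views(p$corners1, p$corners2, checkerboard_spec())
  res <- calibrate_stereo(views)
  write_calibration(res, p$calibration)
  write_error_audit(res, p$error_audit)
  invisible(res)
}

#' Pipeline stage: triangulate the keypoint directories into a skeleton
#'
#' @param cfg A `run_config`; uses the calibration written by
#'   `pipeline_calibrate()`, the configured synchronization offset and
#'   confidence gate.
#' @return The `skeleton3d_series`, invisibly; writes the skeleton CSV.
#' @export
pipeline_reconstruct <- function(cfg) {
  p <- config_paths(cfg)
  s1 <- series_from_directory(p$keypoints1, 1, cfg$frame_rate)
  s2 <- series_from_directory(p$keypoints2, 2, cfg$frame_rate)
  sync <- synchronize_series(s1, s2, cfg$sync_offset)
  calib <- read_calibration(p$calibration)
  skel <- triangulate_series(sync[[1]], sync[[2]], calib, cfg$c_min)
  write_skeleton_csv(skel, p$skeleton)
  invisible(skel)
}

#' Pipeline stage: ergonomic metrics from the skeleton CSV
#'
#' Writes the segment-length summary table (with right-to-left
#' percentage differences), the long-format length time series, and the
#' long-format segment-to-axis angle series.
#'
#' @param cfg A `run_config`.
#' @return List with `lengths` (summary data frame) and `angles` (long
#'   data frame), invisibly.
#' @export
pipeline_metrics <- function(cfg) {
  p <- config_paths(cfg)
  skel <- read_skeleton_csv(p$skeleton, cfg$frame_rate)
  wrot <- matrix(as.numeric(cfg$world_rotation), 3, 3)
  catalog <- segment_catalog()
  lengths <- segment_length_table(skel, catalog)
  utils::write.csv(lengths, p$lengths, row.names = FALSE)
  series_long <- do.call(rbind, lapply(catalog, function(seg) {
    s <- segment_length_series(skel, seg)
    data.frame(segment = seg$name, frame = seq_along(s$length_mm) - 1L,
               time_s = s$time, length_mm = s$length_mm)
  }))
  rownames(series_long) <- NULL
  utils::write.csv(series_long, p$length_series, row.names = FALSE)
  angles <- axis_angle_table(skel, catalog, wrot)
  utils::write.csv(angles, p$angles, row.names = FALSE)
  invisible(list(lengths = lengths, angles = angles))
}
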