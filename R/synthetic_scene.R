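#' Articulated mannequin specification
#'
#' A rigid-limbed 25-keypoint mannequin described by its kinematic tree
#' (rooted at the mid-hip) and the length of every tree edge in mm.
#' Defaults echo plausible reconstructed adult segment lengths: upper arm
#' 255, lower arm 250, upper leg 342, lower leg 380, eye separation 58,
#' neck-shoulder 160, back (neck to mid-hip) 520; the remaining links
#' (head, feet, hip offsets) are anatomically plausible constants.  The
#' mannequin is bilaterally symmetric unless per-side overrides are given.
#'
#' @param lengths Named list overriding any default edge length (keys as
#'   in `mannequin_edges()$length_key`).
#' @param symmetric Keep TRUE for a bilaterally symmetric mannequin;
#'   FALSE only tags the spec, sides are still driven by `lengths`.
#' @return An object of class `mannequin_spec` with an `edges` data frame
#'   (edge_id, parent, child, length_key, side, length_mm).
#' @export
mannequin_spec <- function(lengths = list(), symmetric = TRUE) {
  defaults <- list(back = 520, head = 190, nose_eye = 35, eyes = 58,
                   eye_ear = 75, neck_shoulder = 160, upper_arm = 255,
                   lower_arm = 250, hip_offset = 110, upper_leg = 342,
                   lower_leg = 380, foot = 150, toe = 40, heel = 70)
  for (nm in names(lengths)) {
    if (!nm %in% names(defaults))
      stop(sprintf("unknown segment length '%s'", nm))
    defaults[[nm]] <- lengths[[nm]]
  }
  if (any(unlist(defaults) <= 0)) stop("segment lengths must be positive")
  edges <- mannequin_edges()
  edges$length_mm <- unlist(defaults[edges$length_key], use.names = FALSE)
  structure(list(edges = edges, lengths = defaults, symmetric = symmetric),
            class = "mannequin_spec")
}

# Kinematic tree over the BODY_25 indices, rooted at the mid-hip (8).
# Edges are listed in topological order (parents before children); the
# eye pair is chained (nose -> right eye -> left eye) so the inter-eye
# distance is itself a rigid tree edge.
mannequin_edges <- function() {
  e <- rbind(
    c("back",        8,  1, "back",          "central"),
    c("head",        1,  0, "head",          "central"),
    c("eye_r",       0, 15, "nose_eye",      "right"),
    c("eye_lr",     15, 16, "eyes",          "central"),
    c("ear_r",      15, 17, "eye_ear",       "right"),
    c("ear_l",      16, 18, "eye_ear",       "left"),
    c("shoulder_r",  1,  2, "neck_shoulder", "right"),
    c("upper_arm_r", 2,  3, "upper_arm",     "right"),
    c("lower_arm_r", 3,  4, "lower_arm",     "right"),
    c("shoulder_l",  1,  5, "neck_shoulder", "left"),
    c("upper_arm_l", 5,  6, "upper_arm",     "left"),
    c("lower_arm_l", 6,  7, "lower_arm",     "left"),
    c("hip_r",       8,  9, "hip_offset",    "right"),
    c("upper_leg_r", 9, 10, "upper_leg",     "right"),
    c("lower_leg_r", 10, 11, "lower_leg",    "right"),
    c("hip_l",       8, 12, "hip_offset",    "left"),
    c("upper_leg_l", 12, 13, "upper_leg",    "left"),
    c("lower_leg_l", 13, 14, "lower_leg",    "left"),
    c("toe_r",      11, 22, "foot",          "right"),
    c("toe2_r",     22, 23, "toe",           "right"),
    c("heel_r",     11, 24, "heel",          "right"),
    c("toe_l",      14, 19, "foot",          "left"),
    c("toe2_l",     19, 20, "toe",           "left"),
    c("heel_l",     14, 21, "heel",          "left"))
  data.frame(edge_id = e[, 1], parent = as.integer(e[, 2]),
             child = as.integer(e[, 3]), length_key = e[, 4], side = e[, 5])
}

unit <- function(v) v / sqrt(sum(v^2))

# Base unit directions of every tree edge for a neutral seated rider
# facing -z (toward camera 1); world: x right, y down, z depth.
# The rider's right side therefore lies at negative x.
rider_base_directions <- function() {
  mirror <- function(v) c(-v[1], v[2], v[3])
  d <- list(
    back        = c(0, -1, 0),
    head        = unit(c(0, -0.85, -0.53)),
    eye_r       = unit(c(-0.5, -0.55, -0.67)),
    eye_lr      = c(1, 0, 0),
    ear_r       = unit(c(-0.9, 0.1, 0.42)),
    shoulder_r  = unit(c(-0.97, 0.24, 0)),
    upper_arm_r = unit(c(-0.1, 0.72, -0.69)),
    lower_arm_r = unit(c(0, 0.37, -0.93)),
    hip_r       = unit(c(-0.99, 0.14, 0)),
    upper_leg_r = unit(c(-0.05, 0.76, -0.65)),
    lower_leg_r = unit(c(0, 0.95, 0.31)),
    toe_r       = unit(c(0, 0.33, -0.94)),
    toe2_r      = c(-1, 0, 0),
    heel_r      = unit(c(0, 0.39, 0.92)))
  left <- list(
    ear_l = mirror(d$ear_r), shoulder_l = mirror(d$shoulder_r),
    upper_arm_l = mirror(d$upper_arm_r), lower_arm_l = mirror(d$lower_arm_r),
    hip_l = mirror(d$hip_r), upper_leg_l = mirror(d$upper_leg_r),
    lower_leg_l = mirror(d$lower_leg_r), toe_l = mirror(d$toe_r),
    toe2_l = mirror(d$toe2_r), heel_l = mirror(d$heel_r))
  c(d, left)
}

#' Build a mannequin pose from per-edge directions
#'
#' Walks the kinematic tree from the mid-hip, placing each child keypoint
#' at its parent plus the edge's unit direction scaled by the edge
#' length; resulting poses honor the rigid segment lengths exactly.
#'
#' @param spec A `mannequin_spec`.
#' @param root Mid-hip position in world coordinates, mm.
#' @param directions Named list of unit 3-vectors per edge id.
#' @return 25 x 3 matrix of keypoint positions (row i = keypoint i - 1).
#' @export
pose_from_directions <- function(spec, root, directions) {
  pts <- matrix(NA_real_, N_KEYPOINTS, 3)
  pts[9, ] <- root  # mid-hip, index 8
  e <- spec$edges
  for (i in seq_len(nrow(e))) {
    dir <- directions[[e$edge_id[i]]]
    pts[e$child[i] + 1L, ] <- pts[e$parent[i] + 1L, ] +
      unit(dir) * e$length_mm[i]
  }
  dimnames(pts) <- list(body25_names(), c("x", "y", "z"))
  pts
}

#' Posture keyframe
#'
#' A named, timed full-body pose whose segment lengths match the
#' mannequin specification to 1e-9 mm.
#'
#' @param name Posture label.
#' @param time Time in seconds at which the posture is reached.
#' @param points 25 x 3 matrix of keypoint positions, mm.
#' @param spec The `mannequin_spec` the pose must honor.
#' @return An object of class `posture_keyframe`.
#' @export
posture_keyframe <- function(name, time, points, spec) {
  check_edge_lengths(points, spec, tol = 1e-9,
                     context = sprintf("keyframe '%s'", name))
  structure(list(name = name, time = time, points = points),
            class = "posture_keyframe")
}

check_edge_lengths <- function(points, spec, tol, context = "pose") {
  e <- spec$edges
  len <- sqrt(rowSums((points[e$child + 1L, ] - points[e$parent + 1L, ])^2))
  if (max(abs(len - e$length_mm)) > tol)
    stop(sprintf("%s: segment lengths inconsistent with the mannequin spec (max deviation %.3g mm)",
                 context, max(abs(len - e$length_mm))))
  invisible(TRUE)
}

#' Default rider posture keyframes
#'
#' Four riding postures on the reference schedule: straight (1.5 s), bent
#' onto the tank (6.5 s), left turn (14.5 s) and right turn (21.4 s).
#' Postures are produced by rotating the torso/head/arm edge directions
#' of a neutral seated pose: forward pitch for the tank posture, pitch
#' plus lateral roll for the turns.  The legs stay put (feet anchored on
#' the pegs).
#'
#' @param spec A `mannequin_spec`.
#' @param root Mid-hip world position, mm.  The default seats the rider
#'   about 3 m in front of camera 1, slightly below its optical axis.
#' @param schedule A `posture_schedule` naming the four keyframes; must
#'   contain labels "Straight", "On the tank", "Left turn", "Right turn"
#'   in any order.
#' @return List of four `posture_keyframe`s in schedule order.
#' @export
default_rider_keyframes <- function(spec = mannequin_spec(),
                                    root = c(0, 150, 3000),
                                    schedule = default_posture_schedule(1)) {
  base <- rider_base_directions()
  torso_edges <- c("back", "head", "eye_r", "eye_lr", "ear_r", "ear_l",
                   "shoulder_r", "shoulder_l", "upper_arm_r", "upper_arm_l",
                   "lower_arm_r", "lower_arm_l")
  posed <- function(rot) {
    d <- base
    for (nm in torso_edges) d[[nm]] <- as.numeric(rot %*% d[[nm]])
    d
  }
  torso_rotations <- list(
    "Straight"    = diag(3),
    "On the tank" = rot_x(42),
    "Left turn"   = rot_z(20) %*% rot_x(35),
    "Right turn"  = rot_z(-20) %*% rot_x(35))
  lapply(seq_len(nrow(schedule)), function(i) {
    nm <- schedule$name[i]
    if (!nm %in% names(torso_rotations))
      stop(sprintf("no default pose for posture '%s'", nm))
    posture_keyframe(nm, schedule$time_s[i],
                     pose_from_directions(spec, root,
                                          posed(torso_rotations[[nm]])),
                     spec)
  })
}

#' Interpolate keyframes into a rigid-limbed per-frame trajectory
#'
#' Each keypoint is linearly interpolated between consecutive keyframes
#' (held constant before the first and after the last), then every frame
#' is re-projected onto the rigid-limb constraint: walking the kinematic
#' tree, each child is re-placed along the interpolated bone direction at
#' exactly the spec's segment length, so all rigid lengths hold at every
#' frame to 1e-9 mm.
#'
#' @param keyframes List of `posture_keyframe`s with increasing times.
#' @param spec The `mannequin_spec`.
#' @param frame_rate Frames per second.
#' @param duration Clip length in seconds.
#' @return An object of class `mannequin_trajectory`: list with `points`
#'   (25 x 3 x n array, mm), `time` (s), `frame_rate`, `spec`.
#' @export
build_motion <- function(keyframes, spec = mannequin_spec(),
                         frame_rate = 30, duration = 25) {
  if (length(keyframes) < 1) stop("need at least one keyframe")
  times <- vapply(keyframes, `[[`, numeric(1), "time")
  if (is.unsorted(times, strictly = TRUE))
    stop("keyframe times must be strictly increasing")
  for (k in keyframes)
    check_edge_lengths(k$points, spec, tol = 1e-9,
                       context = sprintf("keyframe '%s'", k$name))
  n <- round(duration * frame_rate)
  t <- (seq_len(n) - 1) / frame_rate
  e <- spec$edges
  pts <- array(NA_real_, c(N_KEYPOINTS, 3, n),
               dimnames = list(body25_names(), c("x", "y", "z"), NULL))
  for (j in seq_len(n)) {
    tj <- t[j]
    if (tj <= times[1]) {
      p <- keyframes[[1]]$points
    } else if (tj >= times[length(times)]) {
      p <- keyframes[[length(keyframes)]]$points
    } else {
      k <- findInterval(tj, times)
      w <- (tj - times[k]) / (times[k + 1] - times[k])
      p <- (1 - w) * keyframes[[k]]$points + w * keyframes[[k + 1]]$points
      # restore rigid limb lengths along the interpolated bone directions
      q <- p
      for (i in seq_len(nrow(e))) {
        dir <- p[e$child[i] + 1L, ] - p[e$parent[i] + 1L, ]
        q[e$child[i] + 1L, ] <- q[e$parent[i] + 1L, ] +
          unit(dir) * e$length_mm[i]
      }
      p <- q
    }
    pts[, , j] <- p
  }
  structure(list(points = pts, time = t, frame_rate = frame_rate,
                 spec = spec),
            class = "mannequin_trajectory")
}

#' Virtual two-camera rig
#'
#' Two identical cameras with a converging geometry: camera 1 sits at the
#' world origin looking down +z; camera 2 is rotated relative to it by a
#' yaw (top-view angle, default 25 deg) composed with a pitch (side-view
#' angle, default 30 deg), both about camera-1 axes (yaw first).  The
#' translation places camera 2 so that both optical axes intersect at the
#' convergence distance `d = baseline / (2 sin(theta / 2))`, `theta`
#' being the total relative rotation angle.
#'
#' @param yaw_deg,pitch_deg Relative orientation angles, degrees, each in
#'   (-90, 90).
#' @param baseline_mm Distance between the camera centers, mm (> 0).
#' @param intrinsics Shared `camera_intrinsics`; the default models an
#'   HD 720p webcam with a 60 deg horizontal field of view.
#' @param distortion Shared `distortion_coefficients` (default: none).
#' @param frame_rate Frames per second (default 30).
#' @param image_size Pixel width and height (default 1280 x 720).
#' @return An object of class `virtual_rig`.
#' @export
virtual_rig <- function(yaw_deg = 25, pitch_deg = 30, baseline_mm = 2000,
                        intrinsics = NULL,
                        distortion = distortion_coefficients(),
                        frame_rate = 30, image_size = c(1280, 720)) {
  if (baseline_mm <= 0) stop("baseline must be positive")
  if (abs(yaw_deg) >= 90 || abs(pitch_deg) >= 90)
    stop("rig angles must lie in (-90, 90) degrees")
  if (is.null(intrinsics)) {
    f <- (image_size[1] / 2) / tan(30 * pi / 180)
    intrinsics <- camera_intrinsics(f, f, image_size[1] / 2,
                                    image_size[2] / 2)
  }
  structure(list(yaw_deg = yaw_deg, pitch_deg = pitch_deg,
                 baseline_mm = baseline_mm, intrinsics = intrinsics,
                 distortion = distortion, frame_rate = frame_rate,
                 image_size = image_size),
            class = "virtual_rig")
}

#' Cameras and geometry of a virtual rig
#'
#' @param rig A `virtual_rig`.
#' @return List with `camera1`, `camera2` (`projective_camera`s; the
#'   world frame is the camera-1 frame), `relative_pose`, and
#'   `convergence_mm` (distance from camera 1 to the crossing point of
#'   the optical axes).
#' @export
rig_cameras <- function(rig) {
  r_rel <- rot_x(rig$pitch_deg) %*% rot_y(rig$yaw_deg)  # yaw applied first
  zhat <- c(0, 0, 1)
  # convergence angle between the two optical axes (z of each camera)
  theta <- acos(min(1, sum(zhat * as.numeric(t(r_rel) %*% zhat))))
  d <- rig$baseline_mm / (2 * sin(theta / 2))
  c2 <- d * zhat - d * as.numeric(t(r_rel) %*% zhat)
  rel <- rigid_pose(r_rel, as.numeric(-r_rel %*% c2))
  list(camera1 = projective_camera(rig$intrinsics, rig$distortion,
                                   identity_pose()),
       camera2 = projective_camera(rig$intrinsics, rig$distortion, rel),
       relative_pose = rel,
       convergence_mm = d)
}

#' Detector noise model
#'
#' Emulates the pose detector's measurement noise: isotropic Gaussian
#' pixel noise, independent per-keypoint per-camera dropout, and a
#' confidence model — visible keypoints draw confidences from
#' Beta(`conf_shape1`, `conf_shape2`), dropped keypoints get 0.  When the
#' model is fully noiseless (sigma 0, dropout 0) confidences are pinned
#' at the Beta mean so the dataset is deterministic.
#'
#' @param sigma_px Pixel noise standard deviation (>= 0; default 1).
#' @param dropout Dropout probability per keypoint per camera in [0, 1].
#' @param conf_shape1,conf_shape2 Beta parameters for visible-keypoint
#'   confidences (defaults 8, 2: mean 0.8).
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma_px = 1, dropout = 0.02, conf_shape1 = 8,
                        conf_shape2 = 2, seed = 1L) {
  if (sigma_px < 0) stop("sigma_px must be non-negative")
  if (dropout < 0 || dropout > 1) stop("dropout must lie in [0, 1]")
  structure(list(sigma_px = sigma_px, dropout = dropout,
                 conf_shape1 = conf_shape1, conf_shape2 = conf_shape2,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Render a mannequin trajectory through a virtual rig
#'
#' Projects every keypoint of every frame through both cameras (including
#' lens distortion), adds seeded Gaussian pixel noise, applies dropout
#' and assigns confidences.  Keypoints behind a camera are dropped with a
#' warning; if the entire mannequin is out of view the render fails.
#'
#' @param trajectory A `mannequin_trajectory`.
#' @param rig A `virtual_rig`.
#' @param noise A `noise_model`.
#' @return List with `series1`, `series2` (`keypoint_series`) and
#'   `truth` (the input trajectory, the ground-truth 3D in the world =
#'   camera-1 frame).
#' @export
render_keypoint_series <- function(trajectory, rig,
                                   noise = noise_model(sigma_px = 0,
                                                       dropout = 0)) {
  cams <- rig_cameras(rig)
  n <- length(trajectory$time)
  set.seed(noise$seed)
  deterministic_conf <- noise$sigma_px == 0 && noise$dropout == 0
  conf_mean <- noise$conf_shape1 / (noise$conf_shape1 + noise$conf_shape2)
  render_one <- function(camera, camera_id) {
    X <- Y <- C <- matrix(0, N_KEYPOINTS, n)
    n_behind <- 0L
    for (j in seq_len(n)) {
      p <- trajectory$points[, , j]
      pc <- t(camera$pose$rotation %*% t(p) + camera$pose$translation)
      front <- pc[, 3] > 0
      n_behind <- n_behind + sum(!front)
      if (!any(front)) next
      px <- project_points(camera, p[front, , drop = FALSE])
      if (noise$sigma_px > 0)
        px <- px + matrix(stats::rnorm(length(px), 0, noise$sigma_px),
                          ncol = 2)
      keep <- if (noise$dropout > 0)
        stats::runif(sum(front)) >= noise$dropout else rep(TRUE, sum(front))
      conf <- if (deterministic_conf) rep(conf_mean, sum(front))
      else stats::rbeta(sum(front), noise$conf_shape1, noise$conf_shape2)
      rows <- which(front)[keep]
      X[rows, j] <- px[keep, 1]
      Y[rows, j] <- px[keep, 2]
      C[rows, j] <- conf[keep]
    }
    if (n_behind == n * N_KEYPOINTS)
      stop(sprintf("camera %s: entire mannequin out of view", camera_id))
    if (n_behind > 0)
      warning(sprintf("camera %s: %d keypoint observations behind the camera were dropped",
                      camera_id, n_behind))
    keypoint_series(X, Y, C, rig$frame_rate, camera_id)
  }
  list(series1 = render_one(cams$camera1, 1),
       series2 = render_one(cams$camera2, 2),
       truth = trajectory)
}

#' Render synthetic checkerboard calibration views
#'
#' Places the calibration board at `n_views` sampled poses inside the
#' rig's shared viewing volume, projects the inner corners through both
#' cameras (with distortion), adds seeded Gaussian corner noise, and
#' returns the paired views together with the ground-truth camera
#' parameters for recovery tests.  Sampled poses must keep every corner
#' inside both images; each view retries a bounded number of times before
#' failing.
#'
#' @param spec A `checkerboard_spec`.
#' @param rig A `virtual_rig`.
#' @param n_views Number of board placements (>= 3).
#' @param noise_sd Corner noise standard deviation, px.
#' @param seed Integer seed.
#' @param pose_sampler Optional function(i) returning a `rigid_pose`
#'   (board frame -> world); the default samples tilts up to ~30 deg per
#'   axis and translations around the rig's convergence point.
#' @param max_retries Attempts per view before giving up.
#' @return List with `views` (list of `calibration_view`s) and `truth`
#'   (intrinsics, distortion, relative_pose, board_poses, cameras).
#' @export
render_checkerboard_views <- function(spec, rig, n_views = 15,
                                      noise_sd = 0, seed = 1L,
                                      pose_sampler = NULL,
                                      max_retries = 200) {
  if (n_views < 3) stop("need at least 3 calibration views")
  cams <- rig_cameras(rig)
  obj <- board_object_points(spec)
  center_off <- c((spec$n_cols - 2) * spec$square_size / 2,
                  (spec$n_rows - 2) * spec$square_size / 2, 0)
  d <- cams$convergence_mm
  set.seed(seed)
  if (is.null(pose_sampler)) {
    pose_sampler <- function(i) {
      rot <- rot_z(stats::runif(1, -30, 30)) %*%
        rot_y(stats::runif(1, -30, 30)) %*% rot_x(stats::runif(1, -30, 30))
      ctr <- c(stats::runif(1, -250, 250), stats::runif(1, -200, 200),
               d * stats::runif(1, 0.85, 1.2))
      rigid_pose(rot, ctr - as.numeric(rot %*% center_off))
    }
  }
  w <- rig$image_size[1]; h <- rig$image_size[2]
  in_view <- function(camera, pts_world) {
    pc <- t(camera$pose$rotation %*% t(pts_world) + camera$pose$translation)
    if (any(pc[, 3] <= 0)) return(NULL)
    px <- project_points(camera, pts_world)
    if (any(px[, 1] < 0 | px[, 1] > w | px[, 2] < 0 | px[, 2] > h))
      return(NULL)
    px
  }
  views <- vector("list", n_views)
  board_poses <- vector("list", n_views)
  for (i in seq_len(n_views)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      pose <- pose_sampler(i)
      pts_world <- t(pose$rotation %*% t(obj) + pose$translation)
      px1 <- in_view(cams$camera1, pts_world)
      if (is.null(px1)) next
      px2 <- in_view(cams$camera2, pts_world)
      if (is.null(px2)) next
      if (noise_sd > 0) {
        px1 <- px1 + matrix(stats::rnorm(length(px1), 0, noise_sd), ncol = 2)
        px2 <- px2 + matrix(stats::rnorm(length(px2), 0, noise_sd), ncol = 2)
      }
      views[[i]] <- calibration_view(i, px1, px2, spec)
      board_poses[[i]] <- pose
      ok <- TRUE
      break
    }
    if (!ok)
      stop(sprintf("view %d: no board pose kept all corners visible in both cameras after %d attempts",
                   i, max_retries))
  }
  list(views = views,
       truth = list(intrinsics = rig$intrinsics,
                    distortion = rig$distortion,
                    relative_pose = cams$camera2$pose,
                    board_poses = board_poses,
                    camera1 = cams$camera1, camera2 = cams$camera2))
}

#' Write a keypoint series as per-frame OpenPose-style JSON files
#'
#' One file per frame in the detector's output dialect (`people` list
#' with a flat `pose_keypoints_2d` array of 75 numbers), with the
#' zero-padded frame index in the filename.  Frames whose keypoints are
#' all invalid are written with an empty `people` list.  The files round
#' trip losslessly through `read_openpose_frame()`.
#'
#' @param series A `keypoint_series`.
#' @param directory Output directory (created if missing).
#' @param camera_id Identifier used in the filenames.
#' @return Invisibly, the written file paths.
#' @export
write_openpose_json <- function(series, directory, camera_id = 1) {
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create directory '%s'", directory))
  n <- n_frames(series)
  files <- character(n)
  for (j in seq_len(n)) {
    payload <- if (all(series$C[, j] == 0)) {
      list(version = 1.3, people = list())
    } else {
      pose <- as.numeric(rbind(series$X[, j], series$Y[, j], series$C[, j]))
      list(version = 1.3,
           people = list(list(person_id = list(-1L),
                              pose_keypoints_2d = pose)))
    }
    files[j] <- file.path(directory,
                          sprintf("cam%s_%012d_keypoints.json",
                                  as.character(camera_id), j - 1L))
    jsonlite::write_json(payload, files[j], auto_unbox = TRUE, digits = NA)
  }
  invisible(files)
}
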