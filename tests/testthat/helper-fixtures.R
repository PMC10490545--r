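# shared fixtures: rigs, random rotations, and independent oracles

unit3 <- function(v) v / sqrt(sum(v^2))

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3)
}

test_rig <- function(...) virtual_rig(...)

# calibration from noiseless synthetic boards, cached per session
noiseless_calibration <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      b <- render_checkerboard_views(checkerboard_spec(), test_rig(),
                                     n_views = 12, seed = 11)
      cache <<- calibrate_stereo(b$views)
    }
    cache
  }
})

# ground-truth calibration object built directly from the rig
truth_calibration <- function(rig = test_rig()) {
  cams <- rig_cameras(rig)
  stereo_calibration_result(cams$camera1, cams$camera2)
}

# independent midpoint-method triangulation oracle: closest point between
# the two back-projected rays
midpoint_triangulate <- function(obs1, obs2, calib) {
  n1 <- undistort_point(calib$camera1, obs1)
  n2 <- undistort_point(calib$camera2, obs2)
  rel <- calib$camera2$pose
  c1 <- c(0, 0, 0)
  d1 <- unit3(c(n1, 1))
  c2 <- as.numeric(-t(rel$rotation) %*% rel$translation)
  d2 <- unit3(as.numeric(t(rel$rotation) %*% c(n2, 1)))
  a <- cbind(d1, -d2)
  st <- solve(crossprod(a), crossprod(a, c2 - c1))
  as.numeric((c1 + st[1] * d1 + c2 + st[2] * d2) / 2)
}

# short rider clip + noiseless rendering for reconstruction tests
short_rider_clip <- function(duration = 3, sigma = 0, dropout = 0, seed = 5) {
  spec <- mannequin_spec()
  traj <- build_motion(default_rider_keyframes(spec), spec,
                       duration = duration)
  rend <- render_keypoint_series(traj, test_rig(),
                                 noise_model(sigma_px = sigma,
                                             dropout = dropout, seed = seed))
  rend
}

write_openpose_fixture <- function(dir, frame, x, y, conf) {
  pose <- as.numeric(rbind(x, y, conf))
  f <- file.path(dir, sprintf("cam1_%012d_keypoints.json", frame))
  jsonlite::write_json(
    list(version = 1.3,
         people = list(list(person_id = list(-1L),
                            pose_keypoints_2d = pose))),
    f, auto_unbox = TRUE, digits = NA)
  f
}
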