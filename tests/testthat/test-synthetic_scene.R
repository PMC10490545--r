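test_that("keyframes and interpolated motion honor the rigid segment lengths", {
  spec <- mannequin_spec()
  kf <- default_rider_keyframes(spec)
  e <- spec$edges
  for (k in kf) {
    len <- sqrt(rowSums((k$points[e$child + 1, ] - k$points[e$parent + 1, ])^2))
    expect_lt(max(abs(len - e$length_mm)), 1e-9)
  }
  traj <- build_motion(kf, spec, duration = 25)
  expect_equal(dim(traj$points), c(25, 3, 750))
  worst <- 0
  for (j in seq_len(750)) {
    p <- traj$points[, , j]
    len <- sqrt(rowSums((p[e$child + 1, ] - p[e$parent + 1, ])^2))
    worst <- max(worst, max(abs(len - e$length_mm)))
  }
  expect_lt(worst, 1e-9)
  # at exactly a keyframe time the keyframe pose is reproduced
  j195 <- round(6.5 * 30) + 1  # "On the tank" at 6.5 s
  expect_equal(traj$points[, , j195], kf[[2]]$points, tolerance = 1e-9)
  # single keyframe: constant trajectory
  traj1 <- build_motion(kf[1], spec, duration = 1)
  expect_equal(traj1$points[, , 30], traj1$points[, , 1])
  # inconsistent keyframe lengths are rejected
  bad <- kf[[1]]
  bad$points[5, 1] <- bad$points[5, 1] + 3
  expect_error(build_motion(list(bad), spec), "inconsistent")
})

test_that("an asymmetric or resized mannequin is honored and invalid lengths rejected", {
  spec <- mannequin_spec(lengths = list(upper_arm = 300, eyes = 62))
  expect_equal(spec$lengths$upper_arm, 300)
  kf <- default_rider_keyframes(spec)
  d <- sqrt(sum((kf[[1]]$points[16, ] - kf[[1]]$points[17, ])^2))
  expect_equal(d, 62, tolerance = 1e-9)
  expect_error(mannequin_spec(lengths = list(eyes = -5)), "positive")
  expect_error(mannequin_spec(lengths = list(femur = 100)), "unknown")
})

test_that("noiseless rendering equals exact projection with confidences at the Beta mean", {
  rend <- short_rider_clip(duration = 0.5)
  cams <- rig_cameras(test_rig())
  for (j in 1:15) {
    exact1 <- project_points(cams$camera1, rend$truth$points[, , j])
    expect_equal(cbind(rend$series1$X[, j], rend$series1$Y[, j]), exact1,
                 tolerance = 1e-9, ignore_attr = TRUE)
    exact2 <- project_points(cams$camera2, rend$truth$points[, , j])
    expect_equal(cbind(rend$series2$X[, j], rend$series2$Y[, j]), exact2,
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  expect_true(all(rend$series1$C == 0.8))  # Beta(8, 2) mean
})

test_that("pixel noise has the configured magnitude and dropout the configured rate", {
  clean <- short_rider_clip(duration = 10)
  noisy <- short_rider_clip(duration = 10, sigma = 1, seed = 31)
  resid <- c(noisy$series1$X - clean$series1$X,
             noisy$series1$Y - clean$series1$Y)
  expect_lt(abs(stats::sd(resid) - 1), 0.05)
  all_drop <- short_rider_clip(duration = 0.5, dropout = 1)
  expect_true(all(all_drop$series1$C == 0))
  expect_true(all(all_drop$series1$X == 0))
})

test_that("identical seeds reproduce identical datasets", {
  a <- short_rider_clip(duration = 1, sigma = 1, dropout = 0.1, seed = 5)
  b <- short_rider_clip(duration = 1, sigma = 1, dropout = 0.1, seed = 5)
  expect_identical(a$series1$X, b$series1$X)
  expect_identical(a$series2$C, b$series2$C)
  v1 <- render_checkerboard_views(checkerboard_spec(), test_rig(),
                                  n_views = 5, noise_sd = 0.3, seed = 9)
  v2 <- render_checkerboard_views(checkerboard_spec(), test_rig(),
                                  n_views = 5, noise_sd = 0.3, seed = 9)
  expect_identical(v1$views[[3]]$corners_cam2, v2$views[[3]]$corners_cam2)
})

test_that("checkerboard views carry the full corner grid and their ground truth re-projects exactly", {
  b <- render_checkerboard_views(checkerboard_spec(), test_rig(),
                                 n_views = 4, seed = 2)
  expect_equal(nrow(b$views[[1]]$corners_cam1), 98)
  obj <- board_object_points(checkerboard_spec())
  for (i in 1:4) {
    pts <- t(b$truth$board_poses[[i]]$rotation %*% t(obj) +
               b$truth$board_poses[[i]]$translation)
    expect_equal(project_points(b$truth$camera1, pts),
                 b$views[[i]]$corners_cam1, tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(project_points(b$truth$camera2, pts),
                 b$views[[i]]$corners_cam2, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  expect_error(render_checkerboard_views(checkerboard_spec(), test_rig(),
                                         n_views = 2), "at least 3")
})

test_that("the JSON writer emits one detector-dialect file per frame, losslessly", {
  rend <- short_rider_clip(duration = 0.3, sigma = 0.5, seed = 3)
  d <- withr::local_tempdir()
  files <- write_openpose_json(rend$series1, d, 1)
  expect_equal(length(files), 9)
  expect_true(all(file.exists(files)))
  s <- series_from_directory(d, 1)
  expect_equal(s$X, rend$series1$X, tolerance = 1e-9)
  expect_equal(s$C, rend$series1$C, tolerance = 1e-9)
  # an all-invalid frame round-trips through an empty people list
  empty <- keypoint_series(matrix(0, 25, 1), matrix(0, 25, 1),
                           matrix(0, 25, 1))
  d2 <- withr::local_tempdir()
  f <- write_openpose_json(empty, d2, 1)
  expect_match(readLines(f[1]), '"people":\\[\\]')
})

test_that("mannequins behind a camera are dropped or rejected", {
  spec <- mannequin_spec()
  kf <- default_rider_keyframes(spec, root = c(0, 150, -3000))
  traj <- build_motion(kf[1], spec, duration = 0.1)
  expect_error(
    suppressWarnings(render_keypoint_series(traj, test_rig())),
    "out of view")
})
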