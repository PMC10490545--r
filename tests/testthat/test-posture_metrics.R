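skeleton_from_points <- function(frames) {
  # frames: list of 25 x 3 matrices
  n <- length(frames)
  X <- vapply(frames, function(p) p[, 1], numeric(25))
  Y <- vapply(frames, function(p) p[, 2], numeric(25))
  Z <- vapply(frames, function(p) p[, 3], numeric(25))
  v <- matrix(TRUE, 25, n)
  e <- matrix(0, 25, n)
  skeleton3d_series(X, Y, Z, v, e, e)
}

test_that("segment lengths are per-frame Euclidean distances with missing-frame handling", {
  p <- matrix(0, 25, 3)
  p[3, ] <- c(100, 0, 0)   # keypoint 2 (RShoulder) 100 mm from keypoint 1
  skel <- skeleton_from_points(rep(list(p), 10))
  seg <- segment_definition("test", 1, 2, "right")
  s <- segment_length_series(skel, seg)
  expect_equal(s$length_mm, rep(100, 10))
  expect_equal(s$summary$mu, 100)
  expect_equal(s$summary$sigma, 0)
  # invalidate the distal point in one frame
  skel$valid[3, 4] <- FALSE
  s2 <- segment_length_series(skel, seg)
  expect_true(is.na(s2$length_mm[4]))
  expect_equal(s2$summary$n_valid, 9)
  skel$valid[3, ] <- FALSE
  expect_error(segment_length_series(skel, seg), "no frame")
})

test_that("a noiselessly reconstructed rigid mannequin reports exact segment lengths", {
  rend <- short_rider_clip(duration = 2)
  skel <- triangulate_series(rend$series1, rend$series2,
                             noiseless_calibration())
  s <- segment_length_series(skel, segment_catalog()$upper_arm_r)
  expect_equal(s$summary$mu, 255, tolerance = 1e-8)
  expect_lt(s$summary$sigma, 1e-6)
})

test_that("axis angles follow the direction-cosine geometry", {
  p <- matrix(0, 25, 3)
  p[9, ] <- c(0, 0, 0)       # mid-hip (8)
  p[2, ] <- c(0, -500, 0)    # neck (1): back along -y
  skel <- skeleton_from_points(list(p))
  back <- segment_catalog()$back  # neck -> mid-hip, i.e. +y here
  expect_equal(axis_angle_series(skel, back, "y")$angle_deg, 0)
  expect_equal(axis_angle_series(skel, back, "x")$angle_deg, 90)
  flipped <- segment_definition("back_up", 8, 1)
  expect_equal(axis_angle_series(skel, flipped, "y")$angle_deg, 180)

  set.seed(55)
  for (i in 1:20) {
    q <- p
    q[2, ] <- stats::rnorm(3, sd = 300)
    sk <- skeleton_from_points(list(q))
    cs <- vapply(c("x", "y", "z"), function(ax)
      cos(axis_angle_series(sk, back, ax)$angle_deg * pi / 180), numeric(1))
    expect_equal(sum(cs^2), 1, tolerance = 1e-9)
  }

  # a segment lying in the y-z plane (positive quadrant: both direction
  # cosines non-negative) has complementary y and z angles
  for (i in 1:10) {
    q <- p
    q[2, ] <- c(0, -abs(stats::rnorm(1, 400, 50)),
                -abs(stats::rnorm(1, 100, 80)))
    sk <- skeleton_from_points(list(q))
    ay <- axis_angle_series(sk, back, "y")$angle_deg
    az <- axis_angle_series(sk, back, "z")$angle_deg
    expect_equal(ay + az, 90, tolerance = 1e-9)
  }
})

test_that("side-to-side and reconstructed-to-real percent differences reproduce the reference cells", {
  expect_equal(right_left_percent_diff(254, 257), 1.2)
  expect_equal(right_left_percent_diff(245, 256), 4.3)
  expect_equal(right_left_percent_diff(390, 370), -5.4)
  expect_equal(right_left_percent_diff(200, 200), 0)
  expect_error(right_left_percent_diff(-1, 200), "positive")
  expect_equal(recon_real_percent_diff(62, 58), -6.9)
  expect_equal(recon_real_percent_diff(222, 250), 11.2)
  expect_equal(recon_real_percent_diff(380, 380), 0)
  expect_error(recon_real_percent_diff(0, 100), "positive")
})

test_that("rounding is half away from zero", {
  expect_equal(round_half_away(0.05, 1), 0.1)
  expect_equal(round_half_away(-0.05, 1), -0.1)
  expect_equal(round_half_away(1.25, 1), 1.3)
  expect_equal(round_half_away(-1.25, 1), -1.3)
  expect_equal(round_half_away(2.349, 1), 2.3)
})

test_that("summary statistics match brute-force computation", {
  expect_equal(series_summary(c(1, 3)), list(mu = 2, sigma = sqrt(2),
                                             n_valid = 2))
  expect_equal(series_summary(c(5))$sigma, 0)
  expect_equal(series_summary(rep(7, 20))$sigma, 0)
  expect_error(series_summary(c(NA_real_, NA_real_)), "no valid")
  set.seed(77)
  v <- stats::rnorm(1000, 100, 15)
  s <- series_summary(v)
  mu <- sum(v) / 1000
  expect_equal(s$mu, mu)
  expect_equal(s$sigma, sqrt(sum((v - mu)^2) / 999))
})

test_that("five-number summaries use inclusive linear-interpolation quartiles", {
  expect_equal(five_number_summary(1:5),
               c(min = 1, q1 = 2, median = 3, q3 = 4, max = 5))
  expect_equal(unname(five_number_summary(rep(4.2, 9))), rep(4.2, 5))
  set.seed(88)
  v <- stats::runif(101) * 50
  fn <- five_number_summary(v)
  sv <- sort(v)
  interp <- function(p) {
    h <- (length(sv) - 1) * p + 1
    lo <- floor(h)
    sv[lo] + (h - lo) * (sv[min(lo + 1, length(sv))] - sv[lo])
  }
  expect_equal(unname(fn),
               c(sv[1], interp(0.25), interp(0.5), interp(0.75),
                 sv[length(sv)]))
})

test_that("posture schedules map to nearest frames", {
  sched <- default_posture_schedule(1)
  expect_equal(sched$time_s, c(1.5, 6.5, 14.5, 21.4))
  skel_time <- list(time = (0:749) / 30)
  ann <- annotate_schedule(skel_time, sched)
  expect_equal(ann$markers$frame[2], 195)  # 6.5 s at 30 fps
  expect_true(all(abs(ann$markers$frame_time_s - ann$markers$time_s) <=
                    0.5 / 30 + 1e-12))
  ann0 <- annotate_schedule(skel_time, posture_schedule("start", 0))
  expect_equal(ann0$markers$frame, 0)
  expect_error(
    annotate_schedule(list(time = (0:29) / 30),
                      posture_schedule("late", 5)),
    "late")
  expect_error(posture_schedule(c("a", "b"), c(3, 1)), "increasing")
})

test_that("the summary table pairs sides and reports their percent difference", {
  rend <- short_rider_clip(duration = 1)
  skel <- triangulate_series(rend$series1, rend$series2,
                             noiseless_calibration())
  tab <- segment_length_table(skel)
  expect_equal(nrow(tab), 13)
  ua <- tab[tab$segment %in% c("upper_arm_l", "upper_arm_r"), ]
  expect_equal(ua$right_left_diff_pct,
               rep(right_left_percent_diff(ua$mu_mm[ua$side == "left"],
                                           ua$mu_mm[ua$side == "right"]), 2))
  expect_true(all(is.na(tab$right_left_diff_pct[tab$side == "central"])))
  # symmetric mannequin, exact reconstruction: zero asymmetry
  expect_equal(ua$right_left_diff_pct[1], 0)
})
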