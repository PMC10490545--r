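test_that("board object points span the printed board geometry", {
  spec <- checkerboard_spec(8, 15, 51)
  pts <- board_object_points(spec)
  expect_equal(nrow(pts), 98)  # 7 x 14 inner corners
  expect_equal(unname(apply(pts, 2, max)), c(663, 306, 0))
  # full board span: squares x edge
  expect_equal(spec$n_cols * spec$square_size, 765)
  expect_equal(spec$n_rows * spec$square_size, 408)
  small <- board_object_points(checkerboard_spec(3, 3, 10))
  expect_equal(nrow(small), 4)
  expect_equal(unname(small[, 1:2]),
               matrix(c(0, 10, 0, 10, 0, 0, 10, 10), ncol = 2))
  expect_error(checkerboard_spec(2, 15, 51), "degenerate")
})

test_that("normalized DLT recovers homographies exactly on clean correspondences", {
  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
  h_id <- estimate_homography(sq, sq)
  expect_equal(h_id / h_id[3, 3], diag(3), tolerance = 1e-10)
  h_tr <- estimate_homography(sq, sweep(sq, 2, c(5, -3), "+"))
  expect_equal(h_tr / h_tr[3, 3],
               matrix(c(1, 0, 0, 0, 1, 0, 5, -3, 1), nrow = 3),
               tolerance = 1e-9)
  set.seed(21)
  h_true <- matrix(stats::rnorm(9), 3, 3) + 3 * diag(3)
  h_true <- h_true / h_true[3, 3]
  obj <- cbind(stats::runif(20, -2, 2), stats::runif(20, -2, 2))
  im <- t(h_true %*% t(cbind(obj, 1)))
  im <- im[, 1:2] / im[, 3]
  h_est <- estimate_homography(obj, im)
  expect_equal(h_est, h_true, tolerance = 1e-8)
  expect_error(estimate_homography(obj[1:3, ], im[1:3, ]), "at least 4")
  coll <- cbind(1:10, 2 * (1:10))
  expect_error(estimate_homography(coll, coll + 1), "collinear")
})

test_that("closed-form intrinsics are recovered from synthetic planar views", {
  k_true <- camera_intrinsics(800, 810, 315, 230, skew = 0)
  kmat <- intrinsics_matrix(k_true)
  set.seed(31)
  make_h <- function() {
    r <- rot_z(stats::runif(1, -40, 40)) %*% rot_y(stats::runif(1, -35, 35)) %*%
      rot_x(stats::runif(1, -35, 35))
    t <- c(stats::runif(2, -200, 200), stats::runif(1, 1500, 3000))
    kmat %*% cbind(r[, 1:2], t)
  }
  hs <- replicate(5, make_h(), simplify = FALSE)
  k <- intrinsics_from_homographies(hs)
  expect_equal(k$fx, 800, tolerance = 1e-6)
  expect_equal(k$fy, 810, tolerance = 1e-6)
  expect_equal(k$cx, 315, tolerance = 1e-4)
  expect_equal(k$cy, 230, tolerance = 1e-4)
  expect_error(intrinsics_from_homographies(hs[1:2]), "at least 3")
})

test_that("intrinsics stay within 1% under 0.2 px corner noise (15 views)", {
  rig <- test_rig()
  b <- render_checkerboard_views(checkerboard_spec(), rig, n_views = 15,
                                 noise_sd = 0.2, seed = 13)
  obj <- board_object_points(checkerboard_spec())[, 1:2]
  hs <- lapply(b$views, function(v) estimate_homography(obj, v$corners_cam1))
  k <- intrinsics_from_homographies(hs)
  expect_lt(abs(k$fx - rig$intrinsics$fx) / rig$intrinsics$fx, 0.01)
  expect_lt(abs(k$fy - rig$intrinsics$fy) / rig$intrinsics$fy, 0.01)
})

test_that("board pose extraction from a homography matches the generating pose", {
  k <- camera_intrinsics(900, 905, 320, 240)
  kmat <- intrinsics_matrix(k)
  # frontal board at distance d
  h <- kmat %*% cbind(diag(3)[, 1:2], c(0, 0, 2000))
  pose <- extrinsics_from_homography(h, k)
  expect_equal(pose$rotation, diag(3), tolerance = 1e-8)
  expect_equal(pose$translation, c(0, 0, 2000), tolerance = 1e-8)
  set.seed(41)
  for (i in 1:10) {
    r_true <- rot_z(stats::runif(1, -40, 40)) %*% rot_x(stats::runif(1, -40, 40))
    t_true <- c(stats::runif(2, -300, 300), stats::runif(1, 1000, 3000))
    pose <- extrinsics_from_homography(kmat %*% cbind(r_true[, 1:2], t_true), k)
    expect_lt(rotation_angle_between(pose$rotation, r_true), 1e-6)
    expect_equal(det(pose$rotation), 1, tolerance = 1e-10)
    expect_equal(pose$translation, t_true, tolerance = 1e-6)
  }
})

test_that("stereo relative pose recovers the rig geometry and benefits from view averaging", {
  rig <- test_rig()  # 25 deg yaw + 30 deg pitch relative orientation
  cams <- rig_cameras(rig)
  b <- render_checkerboard_views(checkerboard_spec(), rig, n_views = 10,
                                 seed = 23)
  rel <- stereo_relative_pose(b$views, rig$intrinsics, rig$intrinsics)
  expect_lt(rotation_angle_between(rel$rotation, cams$camera2$pose$rotation),
            1e-6)
  expect_equal(rel$translation, cams$camera2$pose$translation,
               tolerance = 1e-5)

  # identical cameras: identity relative pose
  views_same <- lapply(b$views, function(v)
    calibration_view(v$view_id, v$corners_cam1, v$corners_cam1, v$spec))
  rel0 <- stereo_relative_pose(views_same, rig$intrinsics, rig$intrinsics)
  expect_equal(rel0$rotation, diag(3), tolerance = 1e-8)
  expect_equal(rel0$translation, c(0, 0, 0), tolerance = 1e-6)

  # averaging over noisy views beats the typical single view
  bn <- render_checkerboard_views(checkerboard_spec(), rig, n_views = 10,
                                  noise_sd = 0.5, seed = 29)
  err_of <- function(views) rotation_angle_between(
    stereo_relative_pose(views, rig$intrinsics, rig$intrinsics)$rotation,
    cams$camera2$pose$rotation)
  e_all <- err_of(bn$views)
  e_single <- vapply(bn$views, function(v) err_of(list(v)), numeric(1))
  expect_lt(e_all, max(e_single))
  expect_lt(e_all, mean(e_single))
})

test_that("full closed-form pipeline recovers a noiseless two-camera rig", {
  rig <- test_rig()
  cams <- rig_cameras(rig)
  b <- render_checkerboard_views(checkerboard_spec(), rig, n_views = 12,
                                 seed = 11)
  res <- calibrate_stereo(b$views, refine = FALSE)
  for (k in list(res$camera1$intrinsics, res$camera2$intrinsics)) {
    expect_lt(abs(k$fx - rig$intrinsics$fx) / rig$intrinsics$fx, 1e-6)
    expect_lt(abs(k$fy - rig$intrinsics$fy) / rig$intrinsics$fy, 1e-6)
  }
  expect_lt(rotation_angle_between(res$camera2$pose$rotation,
                                   cams$camera2$pose$rotation), 1e-6)
  expect_lt(max(abs(res$camera2$pose$translation -
                    cams$camera2$pose$translation)), 1e-3)
  expect_lt(res$overall_mean_error, 1e-8)
})

test_that("refinement never worsens the fit and improves noisy closed-form estimates", {
  rig <- test_rig()
  # noiseless, initialized at an already-optimal solution: unchanged
  b0 <- render_checkerboard_views(checkerboard_spec(), rig, n_views = 8,
                                  seed = 19)
  init <- calibrate_stereo(b0$views, refine = FALSE)
  ref0 <- refine_calibration(init, b0$views)
  expect_equal(ref0$camera1$intrinsics$fx, init$camera1$intrinsics$fx,
               tolerance = 1e-10)
  expect_lte(ref0$overall_mean_error, init$overall_mean_error + 1e-12)

  bn <- render_checkerboard_views(checkerboard_spec(), rig, n_views = 10,
                                  noise_sd = 0.5, seed = 37)
  closed <- calibrate_stereo(bn$views, refine = FALSE)
  refined <- refine_calibration(closed, bn$views)
  expect_lt(refined$overall_mean_error, closed$overall_mean_error)
  expect_lt(abs(refined$camera1$intrinsics$fx - rig$intrinsics$fx),
            abs(closed$camera1$intrinsics$fx - rig$intrinsics$fx))
})

test_that("the reprojection-error audit matches a brute-force recomputation and the noise scale", {
  rig <- test_rig()
  sigma <- 0.5
  b <- render_checkerboard_views(checkerboard_spec(), rig, n_views = 10,
                                 noise_sd = sigma, seed = 7)
  truth <- stereo_calibration_result(b$truth$camera1, b$truth$camera2,
                                     board_poses = b$truth$board_poses)
  audit <- mean_reprojection_error(truth, b$views, b$truth$board_poses)
  # expected distance of an isotropic 2D Gaussian error: sigma * sqrt(pi/2)
  expect_lt(abs(audit$overall - sigma * sqrt(pi / 2)) / (sigma * sqrt(pi / 2)),
            0.15)
  # brute force: loop over every corner of every view
  obj <- board_object_points(checkerboard_spec())
  brute <- vapply(seq_along(b$views), function(i) {
    pose1 <- b$truth$board_poses[[i]]
    cam1 <- projective_camera(rig$intrinsics, rig$distortion, pose1)
    cam2 <- projective_camera(rig$intrinsics, rig$distortion,
                              compose_pose(b$truth$relative_pose, pose1))
    e <- c(vapply(seq_len(nrow(obj)), function(j)
      reprojection_error(cam1, obj[j, ], b$views[[i]]$corners_cam1[j, ]),
      numeric(1)),
      vapply(seq_len(nrow(obj)), function(j)
        reprojection_error(cam2, obj[j, ], b$views[[i]]$corners_cam2[j, ]),
        numeric(1)))
    mean(e)
  }, numeric(1))
  expect_equal(unname(audit$per_view), brute, tolerance = 1e-9)
  # the overall error is the corner-count-weighted mean of per-view errors
  n <- vapply(b$views, function(v) 2 * nrow(v$corners_cam1), numeric(1))
  expect_equal(audit$overall, sum(audit$per_view * n) / sum(n))
})

test_that("corner datasets and calibration results survive CSV / YAML round trips", {
  rig <- test_rig()
  b <- render_checkerboard_views(checkerboard_spec(), rig, n_views = 4,
                                 seed = 3)
  d <- withr::local_tempdir()
  f1 <- file.path(d, "c1.csv"); f2 <- file.path(d, "c2.csv")
  write_corner_views(b$views, f1, f2)
  views2 <- read_corner_views(f1, f2, checkerboard_spec())
  expect_equal(length(views2), 4)
  expect_equal(views2[[2]]$corners_cam1, b$views[[2]]$corners_cam1,
               tolerance = 1e-9, ignore_attr = TRUE)
  calib <- noiseless_calibration()
  fy <- file.path(d, "calib.yaml")
  write_calibration(calib, fy)
  calib2 <- read_calibration(fy)
  expect_equal(calib2$camera2$pose$rotation, calib$camera2$pose$rotation,
               tolerance = 1e-9)
  expect_equal(calib2$overall_mean_error, calib$overall_mean_error,
               tolerance = 1e-12)
})
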