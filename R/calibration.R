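#' Checkerboard specification
#'
#' Calibration board described by its number of squares per side and the
#' square edge length.  The detectable inner-corner grid is
#' `(n_rows - 1) x (n_cols - 1)`.  The default is an 8 x 15 board of
#' 51 mm squares, i.e. a 408 mm x 765 mm board with a 7 x 14 corner grid.
#'
#' @param n_rows,n_cols Number of squares along each side (>= 3).
#' @param square_size Square edge length, mm.
#' @return An object of class `checkerboard_spec`.
#' @export
checkerboard_spec <- function(n_rows = 8, n_cols = 15, square_size = 51) {
  if (n_rows < 3 || n_cols < 3 || square_size <= 0)
    stop("degenerate checkerboard: need n_rows >= 3, n_cols >= 3, square_size > 0")
  structure(list(n_rows = n_rows, n_cols = n_cols, square_size = square_size),
            class = "checkerboard_spec")
}

#' Planar object points of a checkerboard's inner corners
#'
#' Corners are generated row-major over the inner-corner grid with spacing
#' `square_size`, the origin at the first inner corner, and z = 0 (board
#' plane).
#'
#' @param spec A `checkerboard_spec`.
#' @return An `((n_rows-1)*(n_cols-1)) x 3` matrix of board-frame points, mm.
#' @export
board_object_points <- function(spec) {
  nr <- spec$n_rows - 1
  nc <- spec$n_cols - 1
  g <- expand.grid(col = 0:(nc - 1), row = 0:(nr - 1))
  cbind(x = g$col * spec$square_size,
        y = g$row * spec$square_size,
        z = 0)
}

#' Paired stereo calibration view
#'
#' One board placement observed by both cameras: the inner-corner pixel
#' coordinates in each camera, ordered row-major over the corner grid and
#' consistently across the two lists.
#'
#' @param view_id Identifier (integer or string).
#' @param corners_cam1,corners_cam2 n x 2 matrices of corner pixels.
#' @param spec The `checkerboard_spec` the corners belong to.
#' @return An object of class `calibration_view`.
#' @export
calibration_view <- function(view_id, corners_cam1, corners_cam2, spec) {
  n_expected <- (spec$n_rows - 1) * (spec$n_cols - 1)
  corners_cam1 <- rbind2cols(corners_cam1, 2)
  corners_cam2 <- rbind2cols(corners_cam2, 2)
  if (nrow(corners_cam1) != n_expected || nrow(corners_cam2) != n_expected)
    stop(sprintf("view %s: expected %d corners per camera", view_id, n_expected))
  structure(list(view_id = view_id, corners_cam1 = corners_cam1,
                 corners_cam2 = corners_cam2, spec = spec),
            class = "calibration_view")
}

# Hartley normalization: translate centroid to origin, scale mean distance
# to sqrt(2).  Returns the 3x3 similarity.
hartley_normalization <- function(pts) {
  ctr <- colMeans(pts)
  d <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
  matrix(c(s, 0, 0, 0, s, 0, -s * ctr[1], -s * ctr[2], 1), nrow = 3)
}

#' Estimate a planar homography by normalized DLT
#'
#' Maps board-plane coordinates (x, y) to image pixels with the standard
#' normalized direct linear transform: Hartley normalization of both point
#' sets, SVD null vector of the 2n x 9 design matrix, denormalization, and
#' scaling so that `h[3,3] = 1` when that entry is not vanishing.
#'
#' @param object_xy n x 2 matrix of planar (board) coordinates, mm.
#' @param image_pts n x 2 matrix of pixel coordinates.
#' @return 3x3 homography matrix.
#' @export
estimate_homography <- function(object_xy, image_pts) {
  object_xy <- rbind2cols(object_xy, 2)
  image_pts <- rbind2cols(image_pts, 2)
  n <- nrow(object_xy)
  if (n < 4) stop("homography needs at least 4 correspondences")
  if (nrow(image_pts) != n) stop("point count mismatch")
  t1 <- hartley_normalization(object_xy)
  t2 <- hartley_normalization(image_pts)
  oh <- t(t1 %*% t(cbind(object_xy, 1)))
  ih <- t(t2 %*% t(cbind(image_pts, 1)))
  a <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- oh[i, ]; u <- ih[i, 1]; v <- ih[i, 2]
    a[2 * i - 1, ] <- c(x, 0, 0, 0, -u * x)
    a[2 * i, ] <- c(0, 0, 0, x, -v * x)
  }
  if (nrow(a) < 9) a <- rbind(a, matrix(0, 9 - nrow(a), 9))
  s <- svd(a, nu = 0)
  if (s$d[8] / s$d[1] < 1e-12)
    stop("degenerate configuration: correspondences are (near-)collinear")
  h <- matrix(s$v[, 9], nrow = 3, byrow = TRUE)
  h <- solve(t2) %*% h %*% t1
  if (abs(h[3, 3]) > 1e-12) h <- h / h[3, 3]
  h
}

# Zhang's absolute-conic constraint row for columns i, j of H.
conic_constraint_row <- function(h, i, j) {
  c(h[1, i] * h[1, j],
    h[1, i] * h[2, j] + h[2, i] * h[1, j],
    h[2, i] * h[2, j],
    h[3, i] * h[1, j] + h[1, i] * h[3, j],
    h[3, i] * h[2, j] + h[2, i] * h[3, j],
    h[3, i] * h[3, j])
}

#' Closed-form intrinsics from a set of planar homographies
#'
#' Each board view contributes the two linear constraints of the
#' image-of-the-absolute-conic formulation on the 6-vector parameterizing
#' the symmetric conic matrix; the stacked system is solved by SVD least
#' squares and the intrinsic parameters extracted by the standard
#' back-substitution.  At least 3 views of distinct, non-parallel board
#' orientations are required.  Distortion is not estimated here.
#'
#' @param hs List of 3x3 homographies (one per view).
#' @return A `camera_intrinsics`.
#' @export
intrinsics_from_homographies <- function(hs) {
  if (length(hs) < 3)
    stop("intrinsics estimation needs at least 3 board views")
  v <- do.call(rbind, lapply(hs, function(h) {
    rbind(conic_constraint_row(h, 1, 2),
          conic_constraint_row(h, 1, 1) - conic_constraint_row(h, 2, 2))
  }))
  s <- svd(v, nu = 0)
  # the smallest singular value is the (near-zero) solution direction;
  # a vanishing second-smallest means the null space is not unique
  if (s$d[5] / s$d[1] < 1e-10)
    stop(sprintf(
      "rank-deficient conic constraint system (condition number %.3g); vary the board orientations",
      s$d[1] / s$d[5]))
  b <- s$v[, 6]
  b11 <- b[1]; b12 <- b[2]; b22 <- b[3]; b13 <- b[4]; b23 <- b[5]; b33 <- b[6]
  denom <- b11 * b22 - b12^2
  v0 <- (b12 * b13 - b11 * b23) / denom
  lambda <- b33 - (b13^2 + v0 * (b12 * b13 - b11 * b23)) / b11
  if (lambda / b11 < 0) {  # conic sign ambiguity
    b <- -b
    b11 <- b[1]; b12 <- b[2]; b22 <- b[3]; b13 <- b[4]; b23 <- b[5]; b33 <- b[6]
    denom <- b11 * b22 - b12^2
    v0 <- (b12 * b13 - b11 * b23) / denom
    lambda <- b33 - (b13^2 + v0 * (b12 * b13 - b11 * b23)) / b11
  }
  fx <- sqrt(lambda / b11)
  fy <- sqrt(lambda * b11 / denom)
  skew <- -b12 * fx^2 * fy / lambda
  u0 <- skew * v0 / fy - b13 * fx^2 / lambda
  camera_intrinsics(fx, fy, u0, v0, skew)
}

#' Board pose from a homography and known intrinsics
#'
#' Recovers the board-to-camera rigid pose from `K^-1 H`: the first two
#' rotation columns and the translation up to the scale fixed by the first
#' column's norm; the rotation is completed with the cross product and
#' re-orthonormalized by SVD (nearest rotation).  The sign is chosen so
#' the board lies in front of the camera (positive depth).
#'
#' @param h 3x3 homography (board plane -> image).
#' @param k A `camera_intrinsics`.
#' @return A `rigid_pose` (board frame -> camera frame).
#' @export
extrinsics_from_homography <- function(h, k) {
  m <- solve(intrinsics_matrix(k)) %*% h
  scale <- sqrt(sum(m[, 1]^2))
  if (scale < 1e-12) stop("degenerate homography: near-zero scale")
  m <- m / scale
  if (m[3, 3] < 0) m <- -m  # board must be in front (t_z > 0)
  r1 <- m[, 1]; r2 <- m[, 2]
  r3 <- c(r1[2] * r2[3] - r1[3] * r2[2],
          r1[3] * r2[1] - r1[1] * r2[3],
          r1[1] * r2[2] - r1[2] * r2[1])
  q <- cbind(r1, r2, r3)
  s <- svd(q)
  r <- s$u %*% t(s$v)
  if (det(r) < 0) r <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  rigid_pose(r, m[, 3])
}

# per-view board poses in one camera from its corners
board_poses_one_camera <- function(views, corners_field, k) {
  obj <- board_object_points(views[[1]]$spec)[, 1:2]
  lapply(views, function(v) {
    h <- estimate_homography(obj, v[[corners_field]])
    extrinsics_from_homography(h, k)
  })
}

#' Stereo relative pose from paired board views
#'
#' For each paired view the board pose is estimated in each camera; the
#' per-view relative transforms `R2 R1'` and `t2 - (R2 R1') t1` are then
#' aggregated across views by quaternion averaging (dominant eigenvector
#' of the summed quaternion outer products) and the arithmetic mean of the
#' translations.
#'
#' @param views List of `calibration_view`s.
#' @param k1,k2 `camera_intrinsics` for camera 1 and 2.
#' @return A `rigid_pose` mapping camera-1 coordinates to camera-2
#'   coordinates.
#' @export
stereo_relative_pose <- function(views, k1, k2) {
  if (length(views) < 1) stop("no paired calibration views")
  p1 <- board_poses_one_camera(views, "corners_cam1", k1)
  p2 <- board_poses_one_camera(views, "corners_cam2", k2)
  qsum <- matrix(0, 4, 4)
  tsum <- c(0, 0, 0)
  for (i in seq_along(views)) {
    rrel <- p2[[i]]$rotation %*% t(p1[[i]]$rotation)
    trel <- p2[[i]]$translation - as.numeric(rrel %*% p1[[i]]$translation)
    q <- rotation_to_quaternion(rrel)
    qsum <- qsum + tcrossprod(q)
    tsum <- tsum + trel
  }
  e <- eigen(qsum, symmetric = TRUE)
  r <- quaternion_to_rotation(e$vectors[, 1])
  s <- svd(r)
  rigid_pose(s$u %*% t(s$v), tsum / length(views))
}

#' Stereo calibration result
#'
#' @param camera1,camera2 `projective_camera`s in the convention used
#'   throughout: the world frame is the camera-1 frame, so `camera1` has
#'   the identity pose and `camera2`'s pose is the relative pose (camera-2
#'   from camera-1).
#' @param per_view_errors Named numeric vector of per-view mean
#'   reprojection errors, px.
#' @param per_view_corners Corner counts matching `per_view_errors`.
#' @param board_poses List of per-view board poses in the camera-1 frame.
#' @param status "ok" or a warning string from refinement.
#' @return An object of class `stereo_calibration`.
#' @export
stereo_calibration_result <- function(camera1, camera2,
                                      per_view_errors = numeric(0),
                                      per_view_corners = integer(0),
                                      board_poses = list(),
                                      status = "ok") {
  overall <- if (length(per_view_errors))
    sum(per_view_errors * per_view_corners) / sum(per_view_corners)
  else NA_real_
  structure(list(camera1 = camera1, camera2 = camera2,
                 per_view_errors = per_view_errors,
                 per_view_corners = per_view_corners,
                 overall_mean_error = overall,
                 board_poses = board_poses,
                 status = status),
            class = "stereo_calibration")
}

#' @export
print.stereo_calibration <- function(x, ...) {
  cat("stereo_calibration\n")
  cat(sprintf("  camera 1: fx=%.2f fy=%.2f cx=%.2f cy=%.2f\n",
              x$camera1$intrinsics$fx, x$camera1$intrinsics$fy,
              x$camera1$intrinsics$cx, x$camera1$intrinsics$cy))
  cat(sprintf("  camera 2: fx=%.2f fy=%.2f cx=%.2f cy=%.2f\n",
              x$camera2$intrinsics$fx, x$camera2$intrinsics$fy,
              x$camera2$intrinsics$cx, x$camera2$intrinsics$cy))
  ang <- rotation_angle_between(diag(3), x$camera2$pose$rotation) * 180 / pi
  cat(sprintf("  relative rotation %.2f deg, baseline %.1f mm\n",
              ang, sqrt(sum(x$camera2$pose$translation^2))))
  if (length(x$per_view_errors))
    cat(sprintf("  %d views, overall mean reprojection error %.4f px\n",
                length(x$per_view_errors), x$overall_mean_error))
  invisible(x)
}

#' Mean reprojection error audit of a stereo calibration
#'
#' For every corner of every view: the pixel distance between the observed
#' corner and the projected board point, using the calibrated parameters
#' and the (estimated or supplied) per-view board poses.  Per-view means
#' average over corners and both cameras; the overall mean weights views
#' by corner count.
#'
#' @param result A `stereo_calibration`.
#' @param views List of `calibration_view`s.
#' @param board_poses Optional list of per-view board poses in the
#'   camera-1 frame; re-estimated from the views if missing.
#' @return List with `per_view` (named numeric vector, px) and `overall`
#'   (scalar, px).
#' @export
mean_reprojection_error <- function(result, views, board_poses = NULL) {
  if (is.null(board_poses)) {
    if (length(result$board_poses) == length(views))
      board_poses <- result$board_poses
    else
      board_poses <- board_poses_one_camera(views, "corners_cam1",
                                            result$camera1$intrinsics)
  }
  obj <- board_object_points(views[[1]]$spec)
  rel <- result$camera2$pose
  per_view <- vapply(seq_along(views), function(i) {
    pose1 <- board_poses[[i]]
    cam1 <- projective_camera(result$camera1$intrinsics,
                              result$camera1$distortion, pose1)
    cam2 <- projective_camera(result$camera2$intrinsics,
                              result$camera2$distortion,
                              compose_pose(rel, pose1))
    e1 <- sqrt(rowSums((project_points(cam1, obj) - views[[i]]$corners_cam1)^2))
    e2 <- sqrt(rowSums((project_points(cam2, obj) - views[[i]]$corners_cam2)^2))
    mean(c(e1, e2))
  }, numeric(1))
  names(per_view) <- vapply(views, function(v) as.character(v$view_id),
                            character(1))
  n <- vapply(views, function(v) nrow(v$corners_cam1) + nrow(v$corners_cam2),
              numeric(1))
  list(per_view = per_view, overall = sum(per_view * n) / sum(n))
}

# pack/unpack the refinement parameter vector:
# fx,fy,cx,cy,k1,k2 per camera (12), 6 per view board pose, 6 relative pose
pack_calib_params <- function(result, board_poses) {
  intr <- function(cam) {
    k <- cam$intrinsics; d <- cam$distortion
    c(k$fx, k$fy, k$cx, k$cy, d$k1, d$k2)
  }
  pose6 <- function(p) c(matrix_to_rodrigues(p$rotation), p$translation)
  c(intr(result$camera1), intr(result$camera2),
    unlist(lapply(board_poses, pose6)),
    pose6(result$camera2$pose))
}

unpack_calib_params <- function(par, n_views) {
  cam <- function(v) list(
    intrinsics = camera_intrinsics(v[1], v[2], v[3], v[4]),
    distortion = distortion_coefficients(k1 = v[5], k2 = v[6]))
  pose6 <- function(v) rigid_pose(rodrigues_to_matrix(v[1:3]), v[4:6],
                                  tol = 1e-8)
  c1 <- cam(par[1:6]); c2 <- cam(par[7:12])
  boards <- lapply(seq_len(n_views), function(i) {
    pose6(par[12 + (i - 1) * 6 + 1:6])
  })
  rel <- pose6(par[12 + n_views * 6 + 1:6])
  list(cam1 = c1, cam2 = c2, boards = boards, rel = rel)
}

calib_residuals <- function(par, views, obj) {
  n_views <- length(views)
  u <- unpack_calib_params(par, n_views)
  res <- lapply(seq_len(n_views), function(i) {
    pose1 <- u$boards[[i]]
    cam1 <- projective_camera(u$cam1$intrinsics, u$cam1$distortion, pose1)
    cam2 <- projective_camera(u$cam2$intrinsics, u$cam2$distortion,
                              compose_pose(u$rel, pose1))
    c(project_points(cam1, obj) - views[[i]]$corners_cam1,
      project_points(cam2, obj) - views[[i]]$corners_cam2)
  })
  unlist(res)
}

#' Nonlinear refinement of a stereo calibration
#'
#' Minimizes the total squared reprojection error over both cameras by
#' Levenberg-Marquardt least squares (via \code{minpack.lm::nls.lm}),
#' jointly over the two intrinsic sets, the radial distortion terms k1 and
#' k2 of each camera, the per-view board poses and the relative pose.  If
#' the optimizer fails to improve on the initialization, the best iterate
#' seen is returned with a warning status.
#'
#' @param initial A `stereo_calibration` from the closed-form pipeline.
#' @param views List of `calibration_view`s.
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @return A refined `stereo_calibration`; its `overall_mean_error` never
#'   exceeds the initialization's (up to 1e-12).
#' @export
refine_calibration <- function(initial, views, max_iter = 100) {
  obj <- board_object_points(views[[1]]$spec)
  board_poses <- initial$board_poses
  if (length(board_poses) != length(views))
    board_poses <- board_poses_one_camera(views, "corners_cam1",
                                          initial$camera1$intrinsics)
  par0 <- pack_calib_params(initial, board_poses)
  fit <- minpack.lm::nls.lm(
    par = par0, fn = calib_residuals, views = views, obj = obj,
    control = minpack.lm::nls.lm.control(
      maxiter = max_iter, ftol = 1e-15, ptol = 1e-15, maxfev = 100000))
  r0 <- sum(calib_residuals(par0, views, obj)^2)
  r1 <- sum(fit$fvec^2)
  status <- "ok"
  par <- fit$par
  if (r1 > r0 + 1e-12) {
    warning("refinement did not reduce the reprojection error; keeping initialization")
    par <- par0
    status <- "refinement-diverged"
  }
  u <- unpack_calib_params(par, length(views))
  cam1 <- projective_camera(u$cam1$intrinsics, u$cam1$distortion,
                            identity_pose())
  cam2 <- projective_camera(u$cam2$intrinsics, u$cam2$distortion, u$rel)
  res <- stereo_calibration_result(cam1, cam2, board_poses = u$boards,
                                   status = status)
  audit <- mean_reprojection_error(res, views, u$boards)
  res$per_view_errors <- audit$per_view
  res$per_view_corners <- vapply(
    views, function(v) nrow(v$corners_cam1) + nrow(v$corners_cam2), numeric(1))
  res$overall_mean_error <- audit$overall
  res
}

#' Full stereo calibration from paired corner views
#'
#' Runs the closed-form pipeline (per-camera homographies, conic-based
#' intrinsics, per-view extrinsics, quaternion-averaged relative pose;
#' distortion frozen at zero) and, optionally, the nonlinear refinement.
#'
#' @param views List of `calibration_view`s.
#' @param refine Run the nonlinear refinement (default TRUE).
#' @param max_iter Refinement iteration cap.
#' @return A `stereo_calibration` with the reprojection-error audit filled
#'   in.
#' @export
calibrate_stereo <- function(views, refine = TRUE, max_iter = 100) {
  if (length(views) < 3)
    stop("stereo calibration needs at least 3 paired views")
  obj_xy <- board_object_points(views[[1]]$spec)[, 1:2]
  hs1 <- lapply(views, function(v) estimate_homography(obj_xy, v$corners_cam1))
  hs2 <- lapply(views, function(v) estimate_homography(obj_xy, v$corners_cam2))
  k1 <- intrinsics_from_homographies(hs1)
  k2 <- intrinsics_from_homographies(hs2)
  rel <- stereo_relative_pose(views, k1, k2)
  boards <- board_poses_one_camera(views, "corners_cam1", k1)
  cam1 <- projective_camera(k1, pose = identity_pose())
  cam2 <- projective_camera(k2, pose = rel)
  res <- stereo_calibration_result(cam1, cam2, board_poses = boards)
  audit <- mean_reprojection_error(res, views, boards)
  res$per_view_errors <- audit$per_view
  res$per_view_corners <- vapply(
    views, function(v) nrow(v$corners_cam1) + nrow(v$corners_cam2), numeric(1))
  res$overall_mean_error <- audit$overall
  if (refine) res <- refine_calibration(res, views, max_iter = max_iter)
  res
}

#' Read / write corner datasets and error audits as CSV
#'
#' Corner files have columns `view_id, corner_index, x_px, y_px`, one file
#' per camera; the error audit mirrors the per-view reprojection-error bar
#' chart with columns `view_id, mean_error_px`.
#'
#' @param file1,file2 Corner CSV paths for camera 1 and 2.
#' @param spec A `checkerboard_spec`.
#' @return `read_corner_views`: a list of `calibration_view`s.
#' @export
read_corner_views <- function(file1, file2, spec) {
  d1 <- utils::read.csv(file1)
  d2 <- utils::read.csv(file2)
  ids <- sort(intersect(unique(d1$view_id), unique(d2$view_id)))
  lapply(ids, function(id) {
    s1 <- d1[d1$view_id == id, ]
    s2 <- d2[d2$view_id == id, ]
    s1 <- s1[order(s1$corner_index), ]
    s2 <- s2[order(s2$corner_index), ]
    calibration_view(id, cbind(s1$x_px, s1$y_px), cbind(s2$x_px, s2$y_px),
                     spec)
  })
}

#' @rdname read_corner_views
#' @param views List of `calibration_view`s to write.
#' @export
write_corner_views <- function(views, file1, file2) {
  fmt <- function(field) do.call(rbind, lapply(views, function(v) {
    m <- v[[field]]
    data.frame(view_id = v$view_id, corner_index = seq_len(nrow(m)) - 1L,
               x_px = m[, 1], y_px = m[, 2])
  }))
  utils::write.csv(fmt("corners_cam1"), file1, row.names = FALSE)
  utils::write.csv(fmt("corners_cam2"), file2, row.names = FALSE)
  invisible(c(file1, file2))
}

#' @rdname read_corner_views
#' @param result A calibrated `stereo_calibration`.
#' @param file Output CSV path.
#' @export
write_error_audit <- function(result, file) {
  utils::write.csv(
    data.frame(view_id = names(result$per_view_errors),
               mean_error_px = as.numeric(result$per_view_errors)),
    file, row.names = FALSE)
  invisible(file)
}

#' Save / load a stereo calibration as a YAML config
#'
#' @param result A `stereo_calibration`.
#' @param file Path to the YAML file.
#' @export
write_calibration <- function(result, file) {
  yaml::write_yaml(list(
    camera1 = camera_to_list(result$camera1),
    camera2 = camera_to_list(result$camera2),
    overall_mean_error = result$overall_mean_error,
    per_view_errors = as.list(result$per_view_errors)),
    file, precision = 15)
  invisible(file)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(file) {
  x <- yaml::read_yaml(file)
  per_view <- unlist(x$per_view_errors)
  res <- stereo_calibration_result(camera_from_list(x$camera1),
                                   camera_from_list(x$camera2))
  res$per_view_errors <- per_view
  res$overall_mean_error <- x$overall_mean_error
  res
}
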