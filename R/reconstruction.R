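#' Triangulate one stereo observation into metric 3D
#'
#' Both pixel observations are undistorted to normalized image
#' coordinates; the linear direct-linear-transform system is then built
#' from the normalized projection matrices `P1 = [I | 0]` (the world frame
#' is the camera-1 frame) and `P2 = [R | t]` (the relative pose), stacking
#' per camera the rows `x p3' - p1'` and `y p3' - p2'`, and solved for the
#' homogeneous 3D point by SVD.  Per-camera reprojection errors of the
#' dehomogenized point are returned alongside.
#'
#' @param obs1,obs2 Length-2 pixel observations in camera 1 and 2.
#' @param calib A `stereo_calibration`.
#' @param degeneracy_deg Ray-angle threshold (degrees) below which the
#'   triangulation is flagged as unreliable with a warning (the point is
#'   still returned).  Exactly coincident camera centers are an error.
#' @return List with `point` (length-3, mm), `err1`, `err2` (px).
#' @export
triangulate_point <- function(obs1, obs2, calib, degeneracy_deg = 0.1) {
  rel <- calib$camera2$pose
  if (sqrt(sum(rel$translation^2)) < 1e-9)
    stop("degenerate stereo rig: zero baseline (coincident camera centers)")
  n1 <- undistort_point(calib$camera1, obs1)
  n2 <- undistort_point(calib$camera2, obs2)
  p1 <- cbind(diag(3), c(0, 0, 0))
  p2 <- cbind(rel$rotation, rel$translation)
  a <- rbind(n1[1] * p1[3, ] - p1[1, ],
             n1[2] * p1[3, ] - p1[2, ],
             n2[1] * p2[3, ] - p2[1, ],
             n2[2] * p2[3, ] - p2[2, ])
  s <- svd(a, nu = 0)
  xh <- s$v[, 4]
  if (abs(xh[4]) < 1e-14)
    stop("triangulation degenerate: point at infinity")
  pt <- xh[1:3] / xh[4]
  # ray-angle reliability check (directions in the world = camera-1 frame)
  d1 <- c(n1, 1)
  d1 <- d1 / sqrt(sum(d1^2))
  d2 <- as.numeric(t(rel$rotation) %*% c(n2, 1))
  d2 <- d2 / sqrt(sum(d2^2))
  ang <- acos(min(1, max(-1, sum(d1 * d2)))) * 180 / pi
  if (ang < degeneracy_deg)
    warning(sprintf("near-parallel rays (%.4f deg): triangulation unreliable",
                    ang))
  list(point = pt,
       err1 = reprojection_error(calib$camera1, pt, obs1),
       err2 = reprojection_error(calib$camera2, pt, obs2))
}

#' 3D skeleton series
#'
#' Per-frame triangulated keypoints: 25 x n coordinate matrices (mm) in
#' the world (camera-1) frame, a validity mask, per-camera reprojection
#' errors and frame time stamps.
#'
#' @param X,Y,Z 25 x n coordinate matrices, mm; NA where invalid.
#' @param valid 25 x n logical matrix.
#' @param err1,err2 25 x n reprojection-error matrices, px; NA where
#'   invalid.
#' @param frame_rate Frames per second.
#' @param calibration The `stereo_calibration` used (optional).
#' @return An object of class `skeleton3d_series` with a `time` vector in
#'   seconds (`frame / frame_rate`, frames zero-based).
#' @export
skeleton3d_series <- function(X, Y, Z, valid, err1, err2, frame_rate = 30,
                              calibration = NULL) {
  stopifnot(nrow(X) == N_KEYPOINTS, all(dim(X) == dim(Y)),
            all(dim(X) == dim(Z)), all(dim(X) == dim(valid)))
  rownames(X) <- rownames(Y) <- rownames(Z) <- rownames(valid) <- body25_names()
  structure(list(X = X, Y = Y, Z = Z, valid = valid,
                 err1 = err1, err2 = err2, frame_rate = frame_rate,
                 time = (seq_len(ncol(X)) - 1) / frame_rate,
                 calibration = calibration),
            class = "skeleton3d_series")
}

#' @export
print.skeleton3d_series <- function(x, ...) {
  cat(sprintf("skeleton3d_series: 25 x %d frames @ %g fps, %.1f%% keypoints valid\n",
              ncol(x$X), x$frame_rate, 100 * mean(x$valid)))
  invisible(x)
}

#' Triangulate two synchronized keypoint series
#'
#' Every keypoint/frame entry passing the joint confidence gate in both
#' cameras is triangulated; all others propagate as missing values (NA),
#' never as zeros.
#'
#' @param s1,s2 Synchronized `keypoint_series` of equal length.
#' @param calib A `stereo_calibration`.
#' @param c_min Confidence threshold for the joint validity mask.
#' @return A `skeleton3d_series`.
#' @export
triangulate_series <- function(s1, s2, calib, c_min = 0.1) {
  if (n_frames(s1) != n_frames(s2))
    stop("series must be synchronized to equal length")
  if (s1$frame_rate != s2$frame_rate)
    stop("series disagree on frame rate")
  mask <- validity_mask(s1, s2, c_min)
  n <- n_frames(s1)
  X <- Y <- Z <- E1 <- E2 <- matrix(NA_real_, N_KEYPOINTS, n)
  for (j in seq_len(n)) {
    for (i in which(mask[, j])) {
      tr <- triangulate_point(c(s1$X[i, j], s1$Y[i, j]),
                              c(s2$X[i, j], s2$Y[i, j]), calib)
      X[i, j] <- tr$point[1]; Y[i, j] <- tr$point[2]; Z[i, j] <- tr$point[3]
      E1[i, j] <- tr$err1; E2[i, j] <- tr$err2
    }
  }
  skeleton3d_series(X, Y, Z, mask, E1, E2, s1$frame_rate, calib)
}

#' Per-keypoint reprojection-error summary of a skeleton series
#'
#' Mean reprojection error over the valid frames of each keypoint, per
#' camera — the audit that quantifies how consistently the triangulated
#' skeleton re-projects onto the two detectors' observations.
#'
#' @param series A `skeleton3d_series`.
#' @return Data frame with keypoint_index, keypoint_name, n_valid,
#'   mean_err1_px, mean_err2_px.
#' @export
reconstruction_reprojection_error <- function(series) {
  if (ncol(series$X) == 0) stop("empty skeleton series")
  data.frame(
    keypoint_index = 0:(N_KEYPOINTS - 1L),
    keypoint_name = body25_names(),
    n_valid = rowSums(series$valid),
    mean_err1_px = rowMeans(series$err1, na.rm = TRUE),
    mean_err2_px = rowMeans(series$err2, na.rm = TRUE),
    row.names = NULL)
}

#' Export a skeleton series as CSV
#'
#' Long format: frame, time_s, keypoint_index, keypoint_name, x_mm, y_mm,
#' z_mm, valid, err1_px, err2_px.
#'
#' @param series A `skeleton3d_series`.
#' @param file Output CSV path.
#' @export
write_skeleton_csv <- function(series, file) {
  n <- ncol(series$X)
  d <- data.frame(
    frame = rep(seq_len(n) - 1L, each = N_KEYPOINTS),
    time_s = rep(series$time, each = N_KEYPOINTS),
    keypoint_index = rep(0:(N_KEYPOINTS - 1L), times = n),
    keypoint_name = rep(body25_names(), times = n),
    x_mm = as.numeric(series$X), y_mm = as.numeric(series$Y),
    z_mm = as.numeric(series$Z),
    valid = as.logical(series$valid),
    err1_px = as.numeric(series$err1), err2_px = as.numeric(series$err2))
  utils::write.csv(d, file, row.names = FALSE)
  invisible(file)
}

#' Read a skeleton series back from its CSV export
#'
#' @param file CSV path written by `write_skeleton_csv()`.
#' @param frame_rate Frames per second of the original series.
#' @return A `skeleton3d_series`.
#' @export
read_skeleton_csv <- function(file, frame_rate = 30) {
  d <- utils::read.csv(file)
  n <- max(d$frame) + 1L
  shape <- function(v) matrix(v, N_KEYPOINTS, n)
  skeleton3d_series(shape(d$x_mm), shape(d$y_mm), shape(d$z_mm),
                    shape(d$valid), shape(d$err1_px), shape(d$err2_px),
                    frame_rate)
}
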