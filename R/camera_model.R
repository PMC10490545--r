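#' Camera intrinsic parameters
#'
#' Pinhole intrinsics mapping normalized image coordinates to pixels.  The
#' pixel frame has its origin at the top-left corner, x rightward and
#' y downward; coordinates are continuous (sub-pixel positions are
#' meaningful).
#'
#' @param fx,fy Focal lengths in pixels; must be positive.
#' @param cx,cy Principal point in pixels.
#' @param skew Skew coefficient in pixels (0 for square, axis-aligned
#'   pixels).
#' @return An object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(fx, fy, cx, cy, skew = 0) {
  stopifnot(is.finite(fx), is.finite(fy), is.finite(cx), is.finite(cy),
            is.finite(skew))
  if (fx <= 0 || fy <= 0)
    stop("focal lengths must be positive")
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy, skew = skew),
            class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("camera_intrinsics: fx=%.6g fy=%.6g cx=%.6g cy=%.6g skew=%.6g\n",
              x$fx, x$fy, x$cx, x$cy, x$skew))
  invisible(x)
}

#' Intrinsics as a 3x3 calibration matrix
#'
#' @param k A `camera_intrinsics` object.
#' @return The upper-triangular 3x3 matrix K.
#' @export
intrinsics_matrix <- function(k) {
  matrix(c(k$fx, 0, 0,
           k$skew, k$fy, 0,
           k$cx, k$cy, 1), nrow = 3)
}

#' Lens distortion coefficients
#'
#' Radial-tangential (Brown-Conrady) distortion on normalized image
#' coordinates: three radial terms `k1,k2,k3` on the normalized radius and
#' two tangential terms `p1,p2`.  All zero means an ideal pinhole.
#'
#' @param k1,k2,k3 Radial coefficients (dimensionless).
#' @param p1,p2 Tangential coefficients (dimensionless).
#' @return An object of class `distortion_coefficients`.
#' @export
distortion_coefficients <- function(k1 = 0, k2 = 0, k3 = 0, p1 = 0, p2 = 0) {
  v <- c(k1 = k1, k2 = k2, k3 = k3, p1 = p1, p2 = p2)
  if (!all(is.finite(v)))
    stop("distortion coefficients must be finite")
  structure(as.list(v), class = "distortion_coefficients")
}

is_zero_distortion <- function(d) {
  all(abs(unlist(d)) == 0)
}

#' Rigid pose (world-to-camera transform)
#'
#' A rotation plus translation mapping world coordinates (mm) into the
#' camera frame: `x_cam = R %*% x_world + t`.
#'
#' @param rotation 3x3 proper orthonormal matrix.
#' @param translation Length-3 numeric vector, mm.
#' @param tol Orthonormality tolerance.
#' @return An object of class `rigid_pose`.
#' @export
rigid_pose <- function(rotation, translation = c(0, 0, 0), tol = 1e-10) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3,
            all(is.finite(rotation)), all(is.finite(translation)))
  if (max(abs(crossprod(rotation) - diag(3))) > tol)
    stop("rotation is not orthonormal within tolerance")
  if (abs(det(rotation) - 1) > tol)
    stop("rotation must be proper (det = +1)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_pose")
}

#' Identity rigid pose
#' @return A `rigid_pose` with identity rotation and zero translation.
#' @export
identity_pose <- function() rigid_pose(diag(3), c(0, 0, 0))

#' Compose two rigid poses
#'
#' `compose_pose(a, b)` is the transform applying `b` first, then `a`:
#' `x -> a(b(x))`.
#'
#' @param a,b `rigid_pose` objects.
#' @return The composed `rigid_pose`.
#' @export
compose_pose <- function(a, b) {
  r <- a$rotation %*% b$rotation
  # re-symmetrize against drift before validation
  s <- svd(r)
  r <- s$u %*% t(s$v)
  rigid_pose(r, as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid pose
#' @param a A `rigid_pose`.
#' @return The inverse transform as a `rigid_pose`.
#' @export
invert_pose <- function(a) {
  rt <- t(a$rotation)
  rigid_pose(rt, as.numeric(-rt %*% a$translation))
}

#' Elementary rotations (right-handed, angles in degrees)
#' @param deg Angle in degrees.
#' @return 3x3 rotation matrix.
#' @rdname elementary-rotations
#' @export
rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), nrow = 3)
}

#' @rdname elementary-rotations
#' @export
rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), nrow = 3)
}

#' @rdname elementary-rotations
#' @export
rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), nrow = 3)
}

#' Rodrigues axis-angle vector to rotation matrix
#' @param rvec Length-3 vector; direction is the rotation axis, norm the
#'   angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rodrigues_to_matrix <- function(rvec) {
  theta <- sqrt(sum(rvec^2))
  if (theta < 1e-14) return(diag(3))
  k <- rvec / theta
  kx <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), nrow = 3)
  diag(3) + sin(theta) * kx + (1 - cos(theta)) * (kx %*% kx)
}

#' Rotation matrix to Rodrigues vector
#' @param r 3x3 rotation matrix.
#' @return Length-3 axis-angle vector (radians).
#' @export
matrix_to_rodrigues <- function(r) {
  ct <- (sum(diag(r)) - 1) / 2
  ct <- min(1, max(-1, ct))
  theta <- acos(ct)
  if (theta < 1e-12) return(c(0, 0, 0))
  if (abs(theta - pi) < 1e-6) {
    # near half-turn: axis from the symmetric part
    s <- (r + diag(3)) / 2
    axis <- sqrt(pmax(diag(s), 0))
    i <- which.max(axis)
    if (axis[i] > 0) {
      axis <- s[, i] / axis[i]
      axis <- axis / sqrt(sum(axis^2))
    }
    return(axis * theta)
  }
  axis <- c(r[3, 2] - r[2, 3], r[1, 3] - r[3, 1], r[2, 1] - r[1, 2]) /
    (2 * sin(theta))
  axis * theta
}

#' Angle of the rotation taking one rotation matrix to another
#' @param r1,r2 3x3 rotation matrices.
#' @return Angle in radians of `r2 %*% t(r1)`.
#' @export
rotation_angle_between <- function(r1, r2) {
  ct <- (sum(diag(r2 %*% t(r1))) - 1) / 2
  acos(min(1, max(-1, ct)))
}

rotation_to_quaternion <- function(r) {
  tr <- sum(diag(r))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (r[3, 2] - r[2, 3]) / s, (r[1, 3] - r[3, 1]) / s,
           (r[2, 1] - r[1, 2]) / s)
  } else {
    i <- which.max(diag(r))
    j <- i %% 3 + 1
    k <- j %% 3 + 1
    s <- sqrt(r[i, i] - r[j, j] - r[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (r[k, j] - r[j, k]) / s
    q[i + 1] <- s / 4
    q[j + 1] <- (r[j, i] + r[i, j]) / s
    q[k + 1] <- (r[k, i] + r[i, k]) / s
  }
  q / sqrt(sum(q^2))
}

quaternion_to_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3)
}

#' Projective camera
#'
#' Bundles intrinsics, lens distortion and a rigid world-to-camera pose
#' into a full projection model (world mm -> pixel).
#'
#' @param intrinsics A `camera_intrinsics`.
#' @param distortion A `distortion_coefficients` (default: none).
#' @param pose A `rigid_pose` (default: identity, i.e. camera at the world
#'   origin looking down +z).
#' @return An object of class `projective_camera`.
#' @export
projective_camera <- function(intrinsics,
                              distortion = distortion_coefficients(),
                              pose = identity_pose()) {
  stopifnot(inherits(intrinsics, "camera_intrinsics"),
            inherits(distortion, "distortion_coefficients"),
            inherits(pose, "rigid_pose"))
  structure(list(intrinsics = intrinsics, distortion = distortion,
                 pose = pose),
            class = "projective_camera")
}

# Apply the distortion polynomial to normalized coordinates.
# xn: n x 2 matrix of normalized (undistorted) coordinates.
apply_distortion <- function(xn, d) {
  x <- xn[, 1]; y <- xn[, 2]
  r2 <- x^2 + y^2
  radial <- 1 + d$k1 * r2 + d$k2 * r2^2 + d$k3 * r2^3
  dx <- 2 * d$p1 * x * y + d$p2 * (r2 + 2 * x^2)
  dy <- d$p1 * (r2 + 2 * y^2) + 2 * d$p2 * x * y
  cbind(x * radial + dx, y * radial + dy)
}

#' Project world points to pixel coordinates
#'
#' Applies the rigid pose, perspective division, the distortion polynomial
#' and finally the intrinsics.  Points must have positive depth in the
#' camera frame.
#'
#' @param camera A `projective_camera`.
#' @param points_world Numeric n x 3 matrix (or length-3 vector) of world
#'   coordinates, mm.
#' @return n x 2 matrix of pixel coordinates.
#' @export
project_points <- function(camera, points_world) {
  p <- rbind2cols(points_world, 3)
  pc <- t(camera$pose$rotation %*% t(p) + camera$pose$translation)
  if (any(pc[, 3] <= 0))
    stop("point(s) behind the camera (non-positive depth)")
  xn <- pc[, 1:2, drop = FALSE] / pc[, 3]
  xd <- apply_distortion(xn, camera$distortion)
  k <- camera$intrinsics
  cbind(k$fx * xd[, 1] + k$skew * xd[, 2] + k$cx,
        k$fy * xd[, 2] + k$cy)
}

#' @rdname project_points
#' @param point_world Single world point (length-3).
#' @export
project_point <- function(camera, point_world) {
  as.numeric(project_points(camera, matrix(point_world, nrow = 1)))
}

# coerce a vector or matrix to an n x k matrix
rbind2cols <- function(x, k) {
  if (is.null(dim(x))) x <- matrix(x, ncol = k, byrow = FALSE)
  x <- as.matrix(x)
  stopifnot(ncol(x) == k)
  x
}

#' Undistort pixel coordinates to normalized image coordinates
#'
#' Inverts the intrinsics and then the distortion map by fixed-point
#' iteration (at most `max_iter` sweeps, convergence tolerance `tol` in
#' normalized units).
#'
#' @param camera A `projective_camera` (pose is ignored).
#' @param pixels n x 2 matrix (or length-2 vector) of pixel coordinates.
#' @param max_iter Maximum fixed-point iterations.
#' @param tol Convergence tolerance in normalized units.
#' @return n x 2 matrix of ideal (undistorted) normalized coordinates.
#' @export
undistort_points <- function(camera, pixels, max_iter = 50, tol = 1e-12) {
  px <- rbind2cols(pixels, 2)
  if (!all(is.finite(px))) stop("pixel coordinates must be finite")
  k <- camera$intrinsics
  yd <- (px[, 2] - k$cy) / k$fy
  xd <- (px[, 1] - k$cx - k$skew * yd) / k$fx
  d <- camera$distortion
  if (is_zero_distortion(d)) return(cbind(xd, yd))
  x <- xd; y <- yd
  for (i in seq_len(max_iter)) {
    r2 <- x^2 + y^2
    radial <- 1 + d$k1 * r2 + d$k2 * r2^2 + d$k3 * r2^3
    tx <- 2 * d$p1 * x * y + d$p2 * (r2 + 2 * x^2)
    ty <- d$p1 * (r2 + 2 * y^2) + 2 * d$p2 * x * y
    xn <- (xd - tx) / radial
    yn <- (yd - ty) / radial
    delta <- max(abs(xn - x), abs(yn - y))
    x <- xn; y <- yn
    if (delta < tol) return(cbind(x, y))
  }
  bad <- which.max((x - xd)^2 + (y - yd)^2)
  stop(sprintf(
    "undistortion did not converge within %d iterations (pixel %.3f, %.3f)",
    max_iter, px[bad, 1], px[bad, 2]))
}

#' @rdname undistort_points
#' @param pixel Single pixel (length-2).
#' @export
undistort_point <- function(camera, pixel, max_iter = 50, tol = 1e-12) {
  as.numeric(undistort_points(camera, matrix(pixel, nrow = 1),
                              max_iter = max_iter, tol = tol))
}

#' Reprojection error of a world point against an observation
#'
#' Euclidean pixel distance between the projection of `point_world` and an
#' observed pixel position.
#'
#' @param camera A `projective_camera`.
#' @param point_world Length-3 world point, mm.
#' @param observed Length-2 observed pixel position.
#' @return Non-negative scalar, pixels.
#' @export
reprojection_error <- function(camera, point_world, observed) {
  pr <- project_point(camera, point_world)
  sqrt(sum((pr - as.numeric(observed))^2))
}

#' Serialize a projective camera to a list / config file
#'
#' The on-disk format is a YAML mapping with fields fx, fy, cx, cy, skew,
#' k1..k3, p1, p2, the 3x3 rotation (row-major) and the translation in mm.
#'
#' @param camera A `projective_camera`.
#' @return A plain list suitable for `yaml::write_yaml()`.
#' @export
camera_to_list <- function(camera) {
  k <- camera$intrinsics; d <- camera$distortion; p <- camera$pose
  list(fx = k$fx, fy = k$fy, cx = k$cx, cy = k$cy, skew = k$skew,
       k1 = d$k1, k2 = d$k2, k3 = d$k3, p1 = d$p1, p2 = d$p2,
       rotation = as.numeric(t(p$rotation)),
       translation = as.numeric(p$translation))
}

#' @rdname camera_to_list
#' @param x A list as produced by `camera_to_list()`.
#' @export
camera_from_list <- function(x) {
  projective_camera(
    camera_intrinsics(x$fx, x$fy, x$cx, x$cy, x$skew),
    distortion_coefficients(x$k1, x$k2, x$k3, x$p1, x$p2),
    rigid_pose(matrix(as.numeric(x$rotation), nrow = 3, byrow = TRUE),
               as.numeric(x$translation)))
}
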