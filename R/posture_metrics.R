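#' Body segment definition
#'
#' A body segment joins two keypoints; its vector runs proximal to
#' distal (e.g. shoulder to elbow for the upper arm, neck to mid-hip for
#' the back).
#'
#' @param name Segment name.
#' @param proximal,distal Keypoint indices (0-24), distinct.
#' @param side "left", "right" or "central".
#' @return An object of class `segment_definition`.
#' @export
segment_definition <- function(name, proximal, distal, side = "central") {
  stopifnot(proximal %in% 0:24, distal %in% 0:24, proximal != distal,
            side %in% c("left", "right", "central"))
  structure(list(name = name, proximal = as.integer(proximal),
                 distal = as.integer(distal), side = side),
            class = "segment_definition")
}

#' Default segment catalog
#'
#' The segments used for the ergonomic length and angle analyses: the eye
#' pair, the neck-shoulder links, upper and lower arms, the head axis
#' (neck to nose), the back (neck to mid-hip), and upper and lower legs.
#' Every reported length/angle quantity maps to exactly one entry.
#'
#' @return Named list of `segment_definition`s.
#' @export
segment_catalog <- function() {
  defs <- list(
    segment_definition("eyes",            15, 16, "central"),
    segment_definition("neck_shoulder_r",  1,  2, "right"),
    segment_definition("neck_shoulder_l",  1,  5, "left"),
    segment_definition("upper_arm_r",      2,  3, "right"),
    segment_definition("upper_arm_l",      5,  6, "left"),
    segment_definition("lower_arm_r",      3,  4, "right"),
    segment_definition("lower_arm_l",      6,  7, "left"),
    segment_definition("head",             1,  0, "central"),
    segment_definition("back",             1,  8, "central"),
    segment_definition("upper_leg_r",      9, 10, "right"),
    segment_definition("upper_leg_l",     12, 13, "left"),
    segment_definition("lower_leg_r",     10, 11, "right"),
    segment_definition("lower_leg_l",     13, 14, "left"))
  stats::setNames(defs, vapply(defs, `[[`, character(1), "name"))
}

segment_vectors <- function(series, segment) {
  ip <- segment$proximal + 1L
  id <- segment$distal + 1L
  ok <- series$valid[ip, ] & series$valid[id, ]
  v <- rbind(series$X[id, ] - series$X[ip, ],
             series$Y[id, ] - series$Y[ip, ],
             series$Z[id, ] - series$Z[ip, ])
  v[, !ok] <- NA_real_
  list(v = v, ok = ok)
}

#' Summary statistics of a length series
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator; 0
#' when a single value) over the valid (non-missing) values.
#'
#' @param values Numeric vector, possibly with NAs.
#' @return List with `mu`, `sigma`, `n_valid`.
#' @export
series_summary <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) == 0) stop("no valid values to summarize")
  list(mu = mean(v),
       sigma = if (length(v) > 1) stats::sd(v) else 0,
       n_valid = length(v))
}

#' Five-number summary (box-plot statistics)
#'
#' Minimum, quartiles and maximum with quartiles computed by linear
#' interpolation of the order statistics (the inclusive method,
#' `quantile(type = 7)`), so box plots drawn from these numbers are
#' reproducible.
#'
#' @param values Numeric vector, possibly with NAs.
#' @return Named numeric vector (min, q1, median, q3, max).
#' @export
five_number_summary <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) == 0) stop("no valid values to summarize")
  q <- stats::quantile(v, probs = c(0, 0.25, 0.5, 0.75, 1), type = 7,
                       names = FALSE)
  stats::setNames(q, c("min", "q1", "median", "q3", "max"))
}

#' Per-frame length series of a body segment
#'
#' Euclidean distance between the segment's endpoints in every frame;
#' missing (NA) wherever either endpoint is invalid.  The summary holds
#' the mean, sample standard deviation and valid-frame count.
#'
#' @param series A `skeleton3d_series`.
#' @param segment A `segment_definition`.
#' @return An object of class `segment_length_series` with fields
#'   `segment`, `length_mm` (per frame, NA = missing), `time`, `summary`.
#' @export
segment_length_series <- function(series, segment) {
  sv <- segment_vectors(series, segment)
  len <- sqrt(colSums(sv$v^2))
  if (!any(is.finite(len)))
    stop(sprintf("segment '%s': no frame has both endpoints valid",
                 segment$name))
  structure(list(segment = segment, length_mm = len, time = series$time,
                 summary = series_summary(len)),
            class = "segment_length_series")
}

#' @export
print.segment_length_series <- function(x, ...) {
  cat(sprintf("segment '%s': mu = %.1f mm, sigma = %.1f mm (n = %d)\n",
              x$segment$name, x$summary$mu, x$summary$sigma,
              x$summary$n_valid))
  invisible(x)
}

#' Per-frame segment-to-axis angle series
#'
#' For each frame, the angle between the segment vector (proximal to
#' distal) and a world coordinate axis:
#' `theta = acos(v . e / |v|)` in degrees, in [0, 180].  Frames with an
#' invalid endpoint or a zero-length vector are missing.  An optional
#' rigid world-alignment rotation re-expresses the camera-1-relative
#' world axes before measuring.
#'
#' @param series A `skeleton3d_series`.
#' @param segment A `segment_definition`.
#' @param axis "x", "y" or "z".
#' @param world_rotation Optional 3x3 rotation applied to the points
#'   before measuring (default identity).
#' @return An object of class `axis_angle_series` with fields `segment`,
#'   `axis`, `angle_deg` (per frame), `time`.
#' @export
axis_angle_series <- function(series, segment, axis = c("x", "y", "z"),
                              world_rotation = NULL) {
  axis <- match.arg(axis)
  sv <- segment_vectors(series, segment)
  v <- sv$v
  if (!is.null(world_rotation)) v <- world_rotation %*% v
  nv <- sqrt(colSums(v^2))
  nv[nv == 0] <- NA_real_
  e <- c(x = 1, y = 2, z = 3)[[axis]]
  ct <- v[e, ] / nv
  ang <- acos(pmin(1, pmax(-1, ct))) * 180 / pi
  structure(list(segment = segment, axis = axis, angle_deg = ang,
                 time = series$time),
            class = "axis_angle_series")
}

#' Signed right-to-left percentage difference of segment lengths
#'
#' `100 * (right - left) / right`, rounded half-away-from-zero to one
#' decimal — the convention used to compare the two body sides.
#'
#' @param left_mean,right_mean Mean segment lengths, mm (> 0).
#' @return Signed percentage, one decimal.
#' @export
right_left_percent_diff <- function(left_mean, right_mean) {
  if (left_mean <= 0 || right_mean <= 0)
    stop("segment means must be positive")
  round_half_away(100 * (right_mean - left_mean) / right_mean, 1)
}

#' Signed reconstructed-to-real percentage difference
#'
#' `100 * (reconstructed - real) / reconstructed`, rounded
#' half-away-from-zero to one decimal — the convention used to compare a
#' reconstructed mean length against the tape-measured one.
#'
#' @param real Real (measured) length, mm (> 0).
#' @param reconstructed_mean Reconstructed mean length, mm (> 0).
#' @return Signed percentage, one decimal.
#' @export
recon_real_percent_diff <- function(real, reconstructed_mean) {
  if (real <= 0 || reconstructed_mean <= 0)
    stop("lengths must be positive")
  round_half_away(100 * (reconstructed_mean - real) / reconstructed_mean, 1)
}

#' Round half away from zero
#'
#' Commercial rounding: ties go away from zero (so 0.05 -> 0.1 and
#' -0.05 -> -0.1 at one decimal), unlike R's banker's rounding.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Posture schedule
#'
#' Labeled posture keyframes: the named riding positions and the times
#' (s) at which each is reached during the acquisition.
#'
#' @param names Character vector of position labels.
#' @param times Non-negative, increasing times in seconds.
#' @return An object of class `posture_schedule` (a data frame).
#' @export
posture_schedule <- function(names, times) {
  stopifnot(length(names) == length(times))
  if (any(times < 0) || is.unsorted(times, strictly = TRUE))
    stop("schedule times must be non-negative and increasing")
  structure(data.frame(name = names, time_s = times),
            class = c("posture_schedule", "data.frame"))
}

#' Reference posture schedules of the two riders
#'
#' Subject 1: straight at 1.5 s, on the tank at 6.5 s, left turn at
#' 14.5 s, right turn at 21.4 s.  Subject 2: straight at 2.3 s, on the
#' tank at 5.5 s, right turn at 11.2 s, left turn at 20.5 s.
#'
#' @param subject 1 or 2.
#' @return A `posture_schedule`.
#' @export
default_posture_schedule <- function(subject = 1) {
  if (subject == 1)
    posture_schedule(c("Straight", "On the tank", "Left turn", "Right turn"),
                     c(1.5, 6.5, 14.5, 21.4))
  else
    posture_schedule(c("Straight", "On the tank", "Right turn", "Left turn"),
                     c(2.3, 5.5, 11.2, 20.5))
}

#' Attach posture-keyframe markers to a time series
#'
#' Maps each scheduled posture time to the nearest frame of the series
#' (marker frame times are within half a frame period of the requested
#' times).
#'
#' @param x A `segment_length_series`, `axis_angle_series` or any object
#'   with `time` (s) and a frame rate implied by its spacing.
#' @param schedule A `posture_schedule`.
#' @return The input with a `markers` data frame attached (name, time_s,
#'   frame, frame_time_s).
#' @export
annotate_schedule <- function(x, schedule) {
  tmax <- max(x$time)
  frame_rate <- 1 / (x$time[2] - x$time[1])
  markers <- lapply(seq_len(nrow(schedule)), function(i) {
    t <- schedule$time_s[i]
    if (t > tmax + 0.5 / frame_rate)
      stop(sprintf("keyframe '%s' at %.2f s is outside the series (%.2f s)",
                   schedule$name[i], t, tmax))
    fr <- round(t * frame_rate)
    data.frame(name = schedule$name[i], time_s = t, frame = fr,
               frame_time_s = fr / frame_rate)
  })
  x$markers <- do.call(rbind, markers)
  x
}

#' Segment-length summary table over a catalog
#'
#' One row per catalog segment with the mean, standard deviation and
#' valid-frame count; paired left/right segments additionally get the
#' signed right-to-left percentage difference.
#'
#' @param series A `skeleton3d_series`.
#' @param catalog Named list of `segment_definition`s.
#' @return Data frame (segment, side, mu_mm, sigma_mm, n_valid,
#'   right_left_diff_pct).
#' @export
segment_length_table <- function(series, catalog = segment_catalog()) {
  rows <- lapply(catalog, function(seg) {
    s <- segment_length_series(series, seg)$summary
    data.frame(segment = seg$name, side = seg$side, mu_mm = s$mu,
               sigma_mm = s$sigma, n_valid = s$n_valid)
  })
  d <- do.call(rbind, rows)
  rownames(d) <- NULL
  d$right_left_diff_pct <- NA_real_
  base <- sub("_(l|r)$", "", d$segment)
  for (b in unique(base[d$side != "central"])) {
    il <- which(base == b & d$side == "left")
    ir <- which(base == b & d$side == "right")
    if (length(il) == 1 && length(ir) == 1) {
      pct <- right_left_percent_diff(d$mu_mm[il], d$mu_mm[ir])
      d$right_left_diff_pct[c(il, ir)] <- pct
    }
  }
  d
}

#' Axis-angle long table over a catalog
#'
#' Per-frame angles of every catalog segment against the three axes, in
#' long format.
#'
#' @param series A `skeleton3d_series`.
#' @param catalog Named list of `segment_definition`s.
#' @param world_rotation Optional world-alignment rotation.
#' @return Data frame (segment, axis, frame, time_s, angle_deg).
#' @export
axis_angle_table <- function(series, catalog = segment_catalog(),
                             world_rotation = NULL) {
  n <- ncol(series$X)
  rows <- lapply(catalog, function(seg) {
    do.call(rbind, lapply(c("x", "y", "z"), function(ax) {
      a <- axis_angle_series(series, seg, ax, world_rotation)
      data.frame(segment = seg$name, axis = ax, frame = seq_len(n) - 1L,
                 time_s = a$time, angle_deg = a$angle_deg)
    }))
  })
  d <- do.call(rbind, rows)
  rownames(d) <- NULL
  d
}
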