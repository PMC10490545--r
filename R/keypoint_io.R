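#' BODY_25 keypoint names
#'
#' The 25-keypoint human skeleton convention of the OpenPose detector:
#' index 0 is the nose, 1 the neck, 2-4 the right arm (shoulder, elbow,
#' wrist), 5-7 the left arm, 8 the mid-hip, 9-11 the right leg (hip, knee,
#' ankle), 12-14 the left leg, 15/16 the right/left eye, 17/18 the ears,
#' and 19-24 the feet (big toe, small toe, heel; left then right).
#'
#' @return Character vector of length 25 (keypoint index = position - 1).
#' @export
body25_names <- function() {
  c("Nose", "Neck",
    "RShoulder", "RElbow", "RWrist",
    "LShoulder", "LElbow", "LWrist",
    "MidHip",
    "RHip", "RKnee", "RAnkle",
    "LHip", "LKnee", "LAnkle",
    "REye", "LEye", "REar", "LEar",
    "LBigToe", "LSmallToe", "LHeel",
    "RBigToe", "RSmallToe", "RHeel")
}

N_KEYPOINTS <- 25L

#' Single-frame keypoint set
#'
#' @param x,y Length-25 pixel coordinates.
#' @param confidence Length-25 detection confidences in [0, 1].
#' @param frame_index Zero-based frame index.
#' @return An object of class `keypoint_frame`.  Keypoints with confidence
#'   0 (the detector also emits coordinates (0, 0) for them) are invalid.
#' @export
keypoint_frame <- function(x, y, confidence, frame_index = 0L) {
  stopifnot(length(x) == N_KEYPOINTS, length(y) == N_KEYPOINTS,
            length(confidence) == N_KEYPOINTS)
  if (any(confidence < 0 | confidence > 1, na.rm = TRUE))
    stop("confidences must lie in [0, 1]")
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 confidence = as.numeric(confidence),
                 frame_index = as.integer(frame_index)),
            class = "keypoint_frame")
}

invalid_keypoint_frame <- function(frame_index = 0L) {
  keypoint_frame(rep(0, N_KEYPOINTS), rep(0, N_KEYPOINTS),
                 rep(0, N_KEYPOINTS), frame_index)
}

#' Keypoint matrix series for one camera
#'
#' The per-camera data model: three 25 x n matrices holding, for each of
#' the 25 keypoints (rows) and each video frame (columns), the pixel x
#' coordinate, the pixel y coordinate, and the detection confidence.
#'
#' @param X,Y,C 25 x n numeric matrices (keypoint x frame).
#' @param frame_rate Frames per second (> 0; 30 for the reference
#'   webcams).
#' @param camera_id Identifier, informational.
#' @return An object of class `keypoint_series`.
#' @export
keypoint_series <- function(X, Y, C, frame_rate = 30, camera_id = NA) {
  stopifnot(nrow(X) == N_KEYPOINTS, all(dim(X) == dim(Y)),
            all(dim(X) == dim(C)))
  if (frame_rate <= 0) stop("frame_rate must be positive")
  rownames(X) <- rownames(Y) <- rownames(C) <- body25_names()
  structure(list(X = X, Y = Y, C = C, frame_rate = frame_rate,
                 camera_id = camera_id),
            class = "keypoint_series")
}

#' @export
print.keypoint_series <- function(x, ...) {
  cat(sprintf("keypoint_series: 25 x %d frames @ %g fps (camera %s)\n",
              ncol(x$X), x$frame_rate, as.character(x$camera_id)))
  invisible(x)
}

n_frames <- function(s) ncol(s$X)

#' Read one OpenPose per-frame JSON file
#'
#' Expects the detector's output dialect: a top-level `people` list whose
#' first entry carries a flat `pose_keypoints_2d` array of 75 numbers
#' (x, y, confidence for each of the 25 keypoints).  An empty `people`
#' list yields an all-invalid frame.  If several people are present the
#' first is taken and a warning is raised (the supported scenes contain a
#' single subject).
#'
#' @param file Path to the JSON file.
#' @param frame_index Frame index to record on the result (default:
#'   parsed from the trailing digit group of the filename, else 0).
#' @return A `keypoint_frame`.
#' @export
read_openpose_frame <- function(file, frame_index = NULL) {
  if (is.null(frame_index)) {
    frame_index <- frame_index_from_filename(file)
    if (is.na(frame_index)) frame_index <- 0L
  }
  x <- tryCatch(jsonlite::fromJSON(file, simplifyVector = FALSE),
                error = function(e)
                  stop(sprintf("malformed keypoint file '%s': %s",
                               file, conditionMessage(e))))
  people <- x$people
  if (is.null(people) || length(people) == 0)
    return(invalid_keypoint_frame(frame_index))
  if (length(people) > 1)
    warning(sprintf("%s: %d people detected, taking the first",
                    file, length(people)))
  pose <- as.numeric(unlist(people[[1]]$pose_keypoints_2d))
  if (length(pose) != 75)
    stop(sprintf("malformed keypoint file '%s': pose array has %d values, expected 75",
                 file, length(pose)))
  m <- matrix(pose, ncol = 3, byrow = TRUE)
  keypoint_frame(m[, 1], m[, 2], m[, 3], frame_index)
}

frame_index_from_filename <- function(file) {
  m <- regmatches(basename(file),
                  regexpr("[0-9]+(?=[^0-9]*$)", basename(file), perl = TRUE))
  if (length(m) == 0) return(NA_integer_)
  as.integer(m)
}

#' Assemble a keypoint series from a directory of per-frame files
#'
#' Files are ordered by the frame index embedded in the filename
#' (trailing digit group).  Missing indices in the range become
#' all-invalid columns and are reported with a warning.
#'
#' @param directory Directory containing one JSON file per frame.
#' @param camera_id Identifier stored on the series.
#' @param frame_rate Frames per second.
#' @param pattern Filename glob for the keypoint files.
#' @return A `keypoint_series`.
#' @export
series_from_directory <- function(directory, camera_id = NA, frame_rate = 30,
                                  pattern = "\\.json$") {
  files <- list.files(directory, pattern = pattern, full.names = TRUE)
  if (length(files) == 0)
    stop(sprintf("no keypoint files found in '%s'", directory))
  idx <- vapply(files, frame_index_from_filename, integer(1))
  if (any(is.na(idx)))
    stop("keypoint filenames must embed a frame index")
  n <- max(idx) + 1L
  X <- Y <- C <- matrix(0, N_KEYPOINTS, n)
  present <- logical(n)
  for (i in seq_along(files)) {
    f <- read_openpose_frame(files[i], idx[i])
    col <- idx[i] + 1L
    X[, col] <- f$x; Y[, col] <- f$y; C[, col] <- f$confidence
    present[col] <- TRUE
  }
  if (!all(present))
    warning(sprintf("missing frame indices (%s): filled with invalid columns",
                    paste(which(!present) - 1L, collapse = ", ")))
  keypoint_series(X, Y, C, frame_rate, camera_id)
}

#' Synchronize two keypoint series by an integer frame offset
#'
#' Shifts series 2 by `offset` frames (column `j` of the output is column
#' `j + offset` of the input) and trims both series to the overlapping
#' length.
#'
#' @param s1,s2 `keypoint_series` objects.
#' @param offset Integer frame shift applied to series 2; its magnitude
#'   must be smaller than both series lengths.
#' @return List of the two trimmed, frame-paired series.
#' @export
synchronize_series <- function(s1, s2, offset = 0L) {
  n1 <- n_frames(s1); n2 <- n_frames(s2)
  offset <- as.integer(offset)
  if (abs(offset) >= min(n1, n2))
    stop(sprintf("offset %d too large for series of lengths %d and %d",
                 offset, n1, n2))
  if (offset >= 0) {
    n <- min(n1, n2 - offset)
    i1 <- seq_len(n)
    i2 <- seq_len(n) + offset
  } else {
    n <- min(n1 + offset, n2)
    i1 <- seq_len(n) - offset
    i2 <- seq_len(n)
  }
  take <- function(s, i, id) keypoint_series(
    s$X[, i, drop = FALSE], s$Y[, i, drop = FALSE], s$C[, i, drop = FALSE],
    s$frame_rate, id)
  list(take(s1, i1, s1$camera_id), take(s2, i2, s2$camera_id))
}

#' Joint validity mask of two synchronized series
#'
#' A keypoint in a frame is usable for triangulation only when it is
#' simultaneously present in both cameras: the mask is TRUE where the
#' confidence reaches `c_min` in BOTH series.
#'
#' @param s1,s2 Synchronized `keypoint_series` of equal length.
#' @param c_min Confidence threshold (default 0.1).
#' @return 25 x n logical matrix.
#' @export
validity_mask <- function(s1, s2, c_min = 0.1) {
  if (n_frames(s1) != n_frames(s2))
    stop("series must be synchronized to equal length")
  s1$C >= c_min & s2$C >= c_min
}

#' Export a keypoint series' matrices as CSV
#'
#' Writes the three keypoint-by-frame matrices stacked in long format:
#' columns keypoint_index, keypoint_name, frame, x_px, y_px, confidence.
#'
#' @param s A `keypoint_series`.
#' @param file Output CSV path.
#' @export
write_keypoint_series_csv <- function(s, file) {
  n <- n_frames(s)
  d <- data.frame(
    keypoint_index = rep(0:(N_KEYPOINTS - 1L), times = n),
    keypoint_name = rep(body25_names(), times = n),
    frame = rep(seq_len(n) - 1L, each = N_KEYPOINTS),
    x_px = as.numeric(s$X), y_px = as.numeric(s$Y),
    confidence = as.numeric(s$C))
  utils::write.csv(d, file, row.names = FALSE)
  invisible(file)
}
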