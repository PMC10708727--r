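#' @title Core sequence containers
#' @description S3 containers for pose keypoint series, IMU streams, label
#'   timelines and whole recordings. Coordinates are normalized image units in
#'   [0, 1]; missing keypoint samples are stored as `NA` internally and only
#'   become the -1 sentinel at fusion time.
#' @name sequences
NULL

.check_times <- function(t, what = "timestamps") {
  if (length(t) == 0L) stop(what, " must be non-empty")
  if (anyNA(t) || !is.numeric(t)) stop(what, " must be numeric and non-NA")
  d <- diff(t)
  if (length(d) && any(d <= 0)) {
    stop(what, " must be strictly increasing; first offending row: ",
         which(d <= 0)[1L] + 1L)
  }
  invisible(TRUE)
}

#' Construct a pose keypoint sequence
#'
#' @param t Numeric vector of timestamps in seconds, strictly increasing.
#' @param x,y Numeric matrices, frames x keypoints, normalized image
#'   coordinates; `NA` marks a missing sample.
#' @param conf Optional confidence matrix in [0, 1]; defaults to 1.
#' @param keypoints Keypoint names; defaults to `colnames(x)`.
#' @return Object of class `pose_sequence`.
#' @export
pose_sequence <- function(t, x, y, conf = NULL, keypoints = colnames(x)) {
  x <- as.matrix(x); y <- as.matrix(y)
  .check_times(t, "pose timestamps")
  if (is.null(keypoints)) stop("keypoint names required")
  if (length(t) != nrow(x) || !identical(dim(x), dim(y)))
    stop("t, x, y dimensions disagree")
  if (ncol(x) != length(keypoints)) stop("keypoint count disagrees with x")
  if (is.null(conf)) conf <- matrix(1, nrow(x), ncol(x))
  conf <- as.matrix(conf)
  if (!identical(dim(conf), dim(x))) stop("conf dimensions disagree with x")
  dimnames(x) <- dimnames(y) <- dimnames(conf) <- list(NULL, keypoints)
  structure(list(t = as.numeric(t), x = x, y = y, conf = conf,
                 keypoints = as.character(keypoints)),
            class = "pose_sequence")
}

#' @export
print.pose_sequence <- function(x, ...) {
  cat(sprintf("<pose_sequence> %d frames, %d keypoints, %.1f-%.1f s\n",
              length(x$t), length(x$keypoints), min(x$t), max(x$t)))
  invisible(x)
}

#' Number of frames in a pose sequence
#' @param seq A `pose_sequence`.
#' @export
n_frames <- function(seq) length(seq$t)

#' Construct an IMU sequence
#'
#' @param location Body location tag (one of the candidate locations).
#' @param t Timestamps in seconds, strictly increasing.
#' @param channels Numeric matrix, samples x 14, columns ordered as
#'   [IMU_CHANNELS]: quaternion, quaternion-rate angular velocity,
#'   acceleration, magnetic field.
#' @return Object of class `imu_sequence`.
#' @export
imu_sequence <- function(location, t, channels) {
  channels <- as.matrix(channels)
  .check_times(t, paste0("IMU timestamps (", location, ")"))
  if (ncol(channels) != 14L)
    stop("IMU sequences carry exactly 14 channels, got ", ncol(channels))
  if (nrow(channels) != length(t)) stop("t and channels disagree")
  qn <- sqrt(rowSums(channels[, 1:4, drop = FALSE]^2))
  if (any(abs(qn - 1) > 1e-6))
    stop("quaternion channels must be unit-norm within 1e-6")
  colnames(channels) <- IMU_CHANNELS
  structure(list(location = as.character(location), t = as.numeric(t),
                 channels = channels),
            class = "imu_sequence")
}

#' @export
print.imu_sequence <- function(x, ...) {
  cat(sprintf("<imu_sequence> %s: %d samples x 14 channels, %.1f-%.1f s\n",
              x$location, length(x$t), min(x$t), max(x$t)))
  invisible(x)
}

#' Construct a label timeline
#'
#' Activity labels are stored as half-open intervals `[start_s, end_s)`.
#'
#' @param start_s,end_s Numeric interval bounds in seconds, `start_s < end_s`.
#' @param activity Character activity names.
#' @return `data.frame` of class `label_timeline`.
#' @export
label_timeline <- function(start_s, end_s, activity) {
  if (length(start_s) != length(end_s) || length(end_s) != length(activity))
    stop("label fields must have equal length")
  if (length(start_s) && any(end_s <= start_s))
    stop("label intervals must have end_s > start_s")
  df <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                   activity = as.character(activity),
                   stringsAsFactors = FALSE)
  df <- df[order(df$start_s), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("label_timeline", "data.frame")
  df
}

#' Total labeled duration of a timeline, in seconds
#' @param labels A `label_timeline`.
#' @export
labeled_duration <- function(labels) sum(labels$end_s - labels$start_s)

.check_label_overlap <- function(labels) {
  if (nrow(labels) < 2L) return(invisible(TRUE))
  lb <- labels[order(labels$start_s), ]
  ov <- lb$start_s[-1L] < lb$end_s[-nrow(lb)] - 1e-12
  if (any(ov)) {
    stop("overlapping label intervals at ",
         sprintf("%.3f s", lb$start_s[-1L][ov][1L]))
  }
  invisible(TRUE)
}

#' Construct a recording
#'
#' A recording bundles one optional pose stream, one IMU stream per sensor
#' location, and the activity label timeline, together with subject and
#' recording identifiers.
#'
#' @param recording_id,subject_id Identifier strings.
#' @param imus Named list of `imu_sequence` objects (names = locations).
#' @param pose A `pose_sequence` or `NULL` (IMU-only recording).
#' @param labels A `label_timeline`.
#' @param pose_rate_hz,imu_rate_hz Nominal sampling rates.
#' @return Object of class `recording`.
#' @export
recording <- function(recording_id, subject_id, imus, pose = NULL, labels,
                      pose_rate_hz = 10, imu_rate_hz = 60) {
  if (length(imus)) {
    locs <- vapply(imus, function(s) s$location, character(1))
    if (anyDuplicated(locs)) stop("duplicate IMU locations")
    names(imus) <- locs
  }
  if (!is.null(pose) && !inherits(pose, "pose_sequence"))
    stop("pose must be a pose_sequence or NULL")
  structure(list(recording_id = as.character(recording_id),
                 subject_id = as.character(subject_id),
                 imus = imus, pose = pose, labels = labels,
                 pose_rate_hz = pose_rate_hz, imu_rate_hz = imu_rate_hz),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s (subject %s): %d IMU stream(s)%s, %d label interval(s)\n",
              x$recording_id, x$subject_id, length(x$imus),
              if (is.null(x[["pose"]])) ", no pose" else
                sprintf(", pose %d frames", length(x[["pose"]]$t)),
              nrow(x$labels)))
  invisible(x)
}
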