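#' Canonical keypoint vocabularies and pipeline defaults
#'
#' The pose model emits 17 named 2D keypoints per frame. Preprocessing merges
#' the five head-related points into a single `head` point and the two hips
#' into a `pelvis` point, leaving 12 keypoints. Five of those double as
#' wearable-sensor candidate locations (wrists, ankles, pelvis); the head is
#' excluded by default as it carries little movement information for the
#' activities of interest.
#'
#' @name keypoints
NULL

#' The 17 raw pose keypoints, in canonical order.
#' @export
KEYPOINTS_17 <- c(
  "nose", "left_eye", "right_eye", "left_ear", "right_ear",
  "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
  "left_wrist", "right_wrist", "left_hip", "right_hip",
  "left_knee", "right_knee", "left_ankle", "right_ankle"
)

#' The 12 consolidated keypoints, in canonical order.
#' @export
KEYPOINTS_12 <- c(
  "head", "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
  "left_wrist", "right_wrist", "pelvis", "left_knee", "right_knee",
  "left_ankle", "right_ankle"
)

.HEAD_PARTS <- c("nose", "left_eye", "right_eye", "left_ear", "right_ear")
.HIP_PARTS <- c("left_hip", "right_hip")

#' Default sensor-candidate locations.
#' @export
DEFAULT_CANDIDATES <- c("left_wrist", "right_wrist", "pelvis",
                        "left_ankle", "right_ankle")

#' The 14 IMU channels per sensor: unit quaternion (4), quaternion-derived
#' angular velocity (4), acceleration in m/s^2 (3), normalized magnetic
#' field (3).
#' @export
IMU_CHANNELS <- c("q_w", "q_x", "q_y", "q_z",
                  "w_0", "w_1", "w_2", "w_3",
                  "a_x", "a_y", "a_z",
                  "m_x", "m_y", "m_z")

#' Pipeline default constants
#'
#' Central record of the toolkit's fixed configuration values:
#' \describe{
#'   \item{min_placement_frames}{500 — minimum frames per activity for
#'     placement ranking (50 s at 10 Hz).}
#'   \item{placement_corpus_frames}{3000 — frames per activity used by the
#'     cross-validated placement metric when available (5 min at 10 Hz).}
#'   \item{window_length}{600 — classification window in samples
#'     (10 s at 60 Hz).}
#'   \item{n_pose_keypoints}{17 — keypoints per raw pose frame.}
#'   \item{pose_rate_hz}{10; \code{imu_rate_hz}: 60.}
#'   \item{gap_max_s}{0.5 — pose gaps longer than this are sentinel-imputed.}
#'   \item{confidence_threshold}{0.3 — keypoints below it count as missing.}
#'   \item{placement_folds}{5 — contiguous-block folds for the placement
#'     metric.}
#'   \item{missing_sentinel}{-1 — imputation value in fused pose columns.}
#' }
#'
#' @return A named list of defaults.
#' @export
har_defaults <- function() {
  list(
    min_placement_frames = 500L,
    placement_corpus_frames = 3000L,
    window_length = 600L,
    n_pose_keypoints = 17L,
    n_consolidated_keypoints = 12L,
    pose_rate_hz = 10,
    imu_rate_hz = 60,
    gap_max_s = 0.5,
    confidence_threshold = 0.3,
    placement_folds = 5L,
    missing_sentinel = -1
  )
}

#' Construct a sensor-candidate set
#'
#' @param names Ordered keypoint names; must be unique and drawn from the 12
#'   consolidated keypoints. Defaults to wrists, pelvis and ankles.
#' @return Character vector of class `candidate_set`.
#' @export
candidate_set <- function(names = DEFAULT_CANDIDATES) {
  names <- as.character(names)
  if (length(names) == 0L) stop("candidate set must be non-empty")
  if (anyDuplicated(names)) stop("candidate names must be unique")
  bad <- setdiff(names, KEYPOINTS_12)
  if (length(bad) > 0L) {
    stop("unknown candidate location(s): ", paste(bad, collapse = ", "))
  }
  structure(names, class = "candidate_set")
}

# map a candidate location to the raw 17-keypoint names that generate it
.candidate_raw_parts <- function(name) {
  if (name == "pelvis") .HIP_PARTS
  else if (name == "head") .HEAD_PARTS
  else name
}
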