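#' @title Keypoint preprocessing
#' @description Phase 1 of the placement pipeline: merge the five head points
#'   and the two hips into single `head`/`pelvis` points (17 -> 12
#'   keypoints), translate each series so its overall mean sits at the image
#'   center (0.5, 0.5), and restrict to the sensor-candidate keypoints.
#'   Keypoints with confidence below the threshold are treated as missing and
#'   excluded from merge means and the centralization mean.
#' @name preprocess
NULL

# mask low-confidence samples to NA
.masked_xy <- function(seq, threshold) {
  bad <- seq$conf < threshold
  x <- seq$x; y <- seq$y
  x[bad] <- NA_real_; y[bad] <- NA_real_
  list(x = x, y = y)
}

.merge_mean <- function(x, cols) {
  m <- x[, cols, drop = FALSE]
  out <- rowMeans(m, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' Consolidate 17 raw keypoints into 12
#'
#' The five head-related keypoints (nose, eyes, ears) are replaced by their
#' per-frame arithmetic mean `head`, and the two hips by their mean `pelvis`;
#' all other keypoints pass through unchanged. Samples below the confidence
#' threshold are excluded from the means; a merged point with no valid
#' constituent in a frame is marked missing for that frame.
#'
#' @param seq A `pose_sequence` carrying the 17 canonical keypoints.
#' @param confidence_threshold Samples below it count as missing
#'   (default 0.3).
#' @return A `pose_sequence` with the 12 consolidated keypoints.
#' @export
consolidate_keypoints <- function(seq,
                                  confidence_threshold = har_defaults()$confidence_threshold) {
  if (setequal(seq$keypoints, KEYPOINTS_12))
    stop("sequence is already consolidated (12 keypoints)")
  missing <- setdiff(KEYPOINTS_17, seq$keypoints)
  if (length(missing))
    stop("missing canonical keypoint(s): ", paste(missing, collapse = ", "))
  m <- .masked_xy(seq, confidence_threshold)
  n <- nrow(m$x)
  x12 <- y12 <- c12 <- matrix(NA_real_, n, length(KEYPOINTS_12),
                              dimnames = list(NULL, KEYPOINTS_12))
  for (kp in setdiff(KEYPOINTS_12, c("head", "pelvis"))) {
    x12[, kp] <- m$x[, kp]; y12[, kp] <- m$y[, kp]
    c12[, kp] <- seq$conf[, kp]
  }
  x12[, "head"] <- .merge_mean(m$x, .HEAD_PARTS)
  y12[, "head"] <- .merge_mean(m$y, .HEAD_PARTS)
  c12[, "head"] <- .merge_mean(seq$conf, .HEAD_PARTS)
  x12[, "pelvis"] <- .merge_mean(m$x, .HIP_PARTS)
  y12[, "pelvis"] <- .merge_mean(m$y, .HIP_PARTS)
  c12[, "pelvis"] <- .merge_mean(seq$conf, .HIP_PARTS)
  # merged/masked values are authoritative now; confidence kept for reporting
  out <- pose_sequence(seq$t, x12, y12, c12, KEYPOINTS_12)
  attr(out, "consolidated") <- TRUE
  out
}

#' Centralize a keypoint series around the image center
#'
#' Applies one global translation to all valid coordinates so that the mean
#' over all valid keypoints and frames equals (0.5, 0.5). A single frame of
#' reference per series preserves inter-keypoint geometry; missing samples
#' are untouched and excluded from the mean.
#'
#' @param seq A `pose_sequence`.
#' @return The translated `pose_sequence`.
#' @export
centralize <- function(seq) {
  vx <- seq$x[!is.na(seq$x)]
  vy <- seq$y[!is.na(seq$y)]
  if (length(vx) == 0L) stop("cannot centralize: all samples missing")
  dx <- 0.5 - mean(vx)
  dy <- 0.5 - mean(vy)
  out <- seq
  out$x <- seq$x + dx
  out$y <- seq$y + dy
  out
}

#' Restrict a consolidated series to the candidate keypoints
#'
#' @param seq A `pose_sequence` over the 12 consolidated keypoints.
#' @param candidates A `candidate_set` (or character vector of consolidated
#'   keypoint names); output keypoint order follows it.
#' @return A `pose_sequence` over the candidates only.
#' @export
select_candidates <- function(seq, candidates = candidate_set()) {
  candidates <- as.character(candidates)
  bad <- setdiff(candidates, seq$keypoints)
  if (length(bad))
    stop("unknown candidate keypoint(s): ", paste(bad, collapse = ", "))
  pose_sequence(seq$t,
                seq$x[, candidates, drop = FALSE],
                seq$y[, candidates, drop = FALSE],
                seq$conf[, candidates, drop = FALSE],
                candidates)
}

#' Run the full preprocessing pipeline on a recording's pose stream
#'
#' consolidate -> centralize -> select, in that order.
#'
#' @param rec A `recording` with a pose stream.
#' @param candidates Candidate keypoints to retain.
#' @param confidence_threshold Confidence cut-off for missingness.
#' @return A centralized candidate-only `pose_sequence`.
#' @export
preprocess_pose <- function(rec, candidates = candidate_set(),
                            confidence_threshold = har_defaults()$confidence_threshold) {
  if (is.null(rec[["pose"]])) stop("recording ", rec$recording_id, " has no pose stream")
  select_candidates(
    centralize(consolidate_keypoints(rec[["pose"]], confidence_threshold)),
    candidates)
}
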