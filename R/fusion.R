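#' @title Multimodal fusion and windowing
#' @description Synchronizes the 10 Hz pose stream with the 60 Hz IMU streams
#'   onto one regular master clock, linearly interpolating pose between
#'   bracketing frames and imputing the -1 sentinel across gaps, then cuts
#'   the fused multivariate series into fixed-length labeled windows for
#'   classification.
#' @name fusion
NULL

#' Interpolate pose features at query times
#'
#' Linear interpolation between bracketing pose frames per coordinate. A
#' query gets the sentinel (-1) in every pose feature when it lies outside
#' the pose time range, when the bracketing frame gap exceeds `gap_max_s`, or
#' when either bracketing value is missing. Queries coinciding with a frame
#' time reproduce that frame exactly.
#'
#' @param pose A `pose_sequence` (any keypoint set), or `NULL`/empty for
#'   all-sentinel output.
#' @param query_times Sorted numeric vector of times, seconds.
#' @param gap_max_s Largest bridgeable frame gap, seconds (default 0.5).
#' @param keypoints Keypoint names for the output columns (defaults to the
#'   pose's own).
#' @return Numeric matrix `length(query_times) x (2 * n_keypoints)` with
#'   columns `<kp>_x, <kp>_y`.
#' @export
interpolate_pose_at <- function(pose, query_times,
                                gap_max_s = har_defaults()$gap_max_s,
                                keypoints = NULL) {
  sentinel <- har_defaults()$missing_sentinel
  if (is.null(keypoints)) {
    keypoints <- if (!is.null(pose)) pose$keypoints else KEYPOINTS_12
  }
  nq <- length(query_times)
  cols <- as.vector(rbind(paste0(keypoints, "_x"), paste0(keypoints, "_y")))
  out <- matrix(sentinel, nq, 2L * length(keypoints),
                dimnames = list(NULL, cols))
  if (is.null(pose) || length(pose$t) == 0L) {
    har_log("warn", "empty pose sequence: all pose features sentinel-coded")
    return(out)
  }
  t <- pose$t
  lo <- findInterval(query_times, t)              # index of frame <= query
  # queries strictly inside the range with a bracketing pair
  inside <- lo >= 1L & lo < length(t)
  gap_ok <- rep(FALSE, nq)
  gap_ok[inside] <- (t[lo[inside] + 1L] - t[lo[inside]]) <= gap_max_s
  at_frame <- lo >= 1L & query_times %in% t
  for (k in seq_along(keypoints)) {
    xk <- pose$x[, keypoints[k]]; yk <- pose$y[, keypoints[k]]
    for (coord in 1:2) {
      v <- if (coord == 1L) xk else yk
      col <- 2L * (k - 1L) + coord
      # exact frame hits: copy, missing stays sentinel
      hit <- at_frame & !is.na(v[pmax(lo, 1L)])
      out[hit, col] <- v[lo[hit]]
      todo <- !at_frame & inside & gap_ok
      if (any(todo)) {
        i0 <- lo[todo]; i1 <- i0 + 1L
        v0 <- v[i0]; v1 <- v[i1]
        w <- (query_times[todo] - t[i0]) / (t[i1] - t[i0])
        val <- v0 + w * (v1 - v0)
        val[is.na(val)] <- sentinel
        out[todo, col] <- val
      }
    }
  }
  out
}

#' Fuse IMU streams and pose into one multivariate series
#'
#' The master clock is a regular grid at `imu_rate_hz` spanning the
#' intersection of the IMU time spans. IMU channels are sampled by nearest
#' neighbor (sensors are assumed time-synchronized, so drift is negligible
#' and quaternions need no interpolation); pose features come from
#' [interpolate_pose_at()]. Column order: one 14-channel block per IMU in
#' `location_order`, then the pose block (2 columns per keypoint). Pose input
#' with 17 keypoints is consolidated and centralized first, giving 24 pose
#' features.
#'
#' @param imus List of `imu_sequence`s with distinct locations.
#' @param pose Optional `pose_sequence` (or `NULL` for IMU-only).
#' @param gap_max_s Largest bridgeable pose gap, seconds.
#' @param imu_rate_hz Master clock rate (default 60).
#' @param location_order Order of IMU blocks; defaults to the order given.
#' @return Object of class `multimodal_series`: list with `t`, `values`
#'   (samples x features), `pose_cols` (logical), `rate_hz`.
#' @export
fuse <- function(imus, pose = NULL, gap_max_s = har_defaults()$gap_max_s,
                 imu_rate_hz = har_defaults()$imu_rate_hz,
                 location_order = NULL) {
  if (length(imus) == 0L) stop("need at least one IMU sequence")
  locs <- vapply(imus, function(s) s$location, character(1))
  if (anyDuplicated(locs)) stop("duplicate IMU locations")
  names(imus) <- locs
  if (is.null(location_order)) location_order <- locs
  if (!setequal(location_order, locs)) stop("location_order must match IMU locations")
  t0 <- max(vapply(imus, function(s) min(s$t), numeric(1)))
  t1 <- min(vapply(imus, function(s) max(s$t), numeric(1)))
  if (t1 <= t0) stop("IMU time spans have empty intersection")
  grid <- seq(t0, t1, by = 1 / imu_rate_hz)
  blocks <- lapply(location_order, function(loc) {
    s <- imus[[loc]]
    # nearest-neighbor sample index for each grid time
    lo <- findInterval(grid, s$t, all.inside = TRUE)
    hi <- pmin(lo + 1L, length(s$t))
    nearest <- ifelse(grid - s$t[lo] <= s$t[hi] - grid, lo, hi)
    b <- s$channels[nearest, , drop = FALSE]
    colnames(b) <- paste(loc, IMU_CHANNELS, sep = ".")
    b
  })
  values <- do.call(cbind, blocks)
  pose_cols <- rep(FALSE, ncol(values))
  if (!is.null(pose)) {
    if (setequal(pose$keypoints, KEYPOINTS_17)) {
      pose <- centralize(consolidate_keypoints(pose))
    }
    pb <- interpolate_pose_at(pose, grid, gap_max_s)
    colnames(pb) <- paste0("pose.", colnames(pb))
    values <- cbind(values, pb)
    pose_cols <- c(pose_cols, rep(TRUE, ncol(pb)))
  }
  if (anyNA(values)) stop("fused series must not contain NaN/NA")
  structure(list(t = grid, values = values, pose_cols = pose_cols,
                 rate_hz = imu_rate_hz),
            class = "multimodal_series")
}

#' @export
print.multimodal_series <- function(x, ...) {
  cat(sprintf("<multimodal_series> %d samples x %d features at %g Hz (%d pose cols)\n",
              length(x$t), ncol(x$values), x$rate_hz, sum(x$pose_cols)))
  invisible(x)
}

#' Cut a fused series into fixed-length labeled windows
#'
#' Windows start at the first sample and advance by `stride`; a trailing
#' partial window is dropped. Each window is labeled by majority occupancy of
#' the label timeline over its time span; windows with no label coverage are
#' dropped.
#'
#' @param series A `multimodal_series`.
#' @param labels A `label_timeline`.
#' @param window_len Window length in samples (default 600 = 10 s at 60 Hz).
#' @param stride Step between window starts in samples (default
#'   `window_len`, i.e. non-overlapping).
#' @param subject_id,recording_id Provenance recorded per window.
#' @return Object of class `windowed_dataset`: list with `X` (array
#'   n x window_len x features), `labels`, `subject_id`, `recording_id`,
#'   `feature_names`, `pose_cols`.
#' @export
make_windows <- function(series, labels,
                         window_len = har_defaults()$window_length,
                         stride = window_len,
                         subject_id = "?", recording_id = "?") {
  if (window_len < 1L || stride < 1L) stop("window_len and stride must be >= 1")
  n <- length(series$t)
  if (n < window_len) {
    warning("series shorter than one window; empty dataset")
    return(.windowed_dataset(array(0, c(0L, window_len, ncol(series$values))),
                             character(0), character(0), character(0),
                             colnames(series$values), series$pose_cols))
  }
  starts <- seq(1L, n - window_len + 1L, by = stride)
  dt <- 1 / series$rate_hz
  win_labels <- character(length(starts))
  for (w in seq_along(starts)) {
    ws <- series$t[starts[w]]
    we <- ws + window_len * dt
    ov <- pmin(labels$end_s, we) - pmax(labels$start_s, ws)
    ov[ov < 0] <- 0
    if (all(ov == 0)) { win_labels[w] <- NA_character_; next }
    occ <- tapply(ov, labels$activity, sum)
    win_labels[w] <- names(occ)[which.max(occ)]
  }
  keep <- !is.na(win_labels)
  starts <- starts[keep]; win_labels <- win_labels[keep]
  X <- array(0, c(length(starts), window_len, ncol(series$values)))
  for (w in seq_along(starts)) {
    X[w, , ] <- series$values[starts[w]:(starts[w] + window_len - 1L), ]
  }
  .windowed_dataset(X, win_labels, rep(subject_id, length(starts)),
                    rep(recording_id, length(starts)),
                    colnames(series$values), series$pose_cols)
}

.windowed_dataset <- function(X, labels, subject_id, recording_id,
                              feature_names, pose_cols) {
  structure(list(X = X, labels = labels, subject_id = subject_id,
                 recording_id = recording_id, feature_names = feature_names,
                 pose_cols = pose_cols),
            class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf("<windowed_dataset> %d windows of %d x %d; %d class(es), %d subject(s)\n",
              dim(x$X)[1], dim(x$X)[2], dim(x$X)[3],
              length(unique(x$labels)), length(unique(x$subject_id))))
  invisible(x)
}

#' Number of windows in a dataset
#' @param dataset A `windowed_dataset`.
#' @export
n_windows <- function(dataset) dim(dataset$X)[1]

#' Concatenate windowed datasets
#' @param datasets List of `windowed_dataset`s with identical features.
#' @return A single `windowed_dataset`.
#' @export
bind_windows <- function(datasets) {
  datasets <- datasets[vapply(datasets, n_windows, integer(1)) > 0L]
  if (length(datasets) == 0L) stop("no non-empty datasets to bind")
  f0 <- datasets[[1L]]$feature_names
  for (d in datasets) {
    if (!identical(d$feature_names, f0)) stop("feature sets differ")
  }
  X <- do.call(abind_first, lapply(datasets, function(d) d$X))
  .windowed_dataset(
    X,
    unlist(lapply(datasets, function(d) d$labels), use.names = FALSE),
    unlist(lapply(datasets, function(d) d$subject_id), use.names = FALSE),
    unlist(lapply(datasets, function(d) d$recording_id), use.names = FALSE),
    f0, datasets[[1L]]$pose_cols)
}

# bind 3D arrays along the first dimension
abind_first <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1L]])
  n <- sum(vapply(arrs, function(a) dim(a)[1L], integer(1)))
  out <- array(0, c(n, d[2L], d[3L]))
  at <- 0L
  for (a in arrs) {
    na <- dim(a)[1L]
    if (na > 0L) out[at + seq_len(na), , ] <- a
    at <- at + na
  }
  out
}

#' Restrict a windowed dataset to one modality
#'
#' Column masking that mirrors a modality-ablation protocol: `"imu"` keeps
#' the 14-channel IMU blocks, `"pose"` the pose features, `"both"` all.
#'
#' @param dataset A `windowed_dataset`.
#' @param modality One of "imu", "pose", "both".
#' @return A `windowed_dataset` over the selected columns.
#' @export
select_modality <- function(dataset, modality = c("both", "imu", "pose")) {
  modality <- match.arg(modality)
  keep <- switch(modality,
                 both = rep(TRUE, length(dataset$pose_cols)),
                 imu = !dataset$pose_cols,
                 pose = dataset$pose_cols)
  if (!any(keep)) stop("no columns for modality ", modality)
  .windowed_dataset(dataset$X[, , keep, drop = FALSE], dataset$labels,
                    dataset$subject_id, dataset$recording_id,
                    dataset$feature_names[keep], dataset$pose_cols[keep])
}

#' Fuse and window one recording
#'
#' Convenience wrapper: [fuse()] the recording's streams, then
#' [make_windows()] with its label timeline and provenance.
#'
#' @param rec A `recording`.
#' @param window_len,stride Window geometry in samples.
#' @param modality One of "both", "imu", "pose".
#' @param gap_max_s Largest bridgeable pose gap, seconds.
#' @return A `windowed_dataset`.
#' @export
windows_from_recording <- function(rec,
                                   window_len = har_defaults()$window_length,
                                   stride = window_len,
                                   modality = "both",
                                   gap_max_s = har_defaults()$gap_max_s) {
  series <- fuse(rec$imus, rec[["pose"]], gap_max_s, rec$imu_rate_hz)
  ds <- make_windows(series, rec$labels, window_len, stride,
                     subject_id = rec$subject_id,
                     recording_id = rec$recording_id)
  if (modality != "both") ds <- select_modality(ds, modality)
  ds
}

#' Fuse and window many recordings into one dataset
#' @param recordings List of `recording`s.
#' @inheritParams windows_from_recording
#' @return A `windowed_dataset`.
#' @export
build_dataset <- function(recordings,
                          window_len = har_defaults()$window_length,
                          stride = window_len, modality = "both",
                          gap_max_s = har_defaults()$gap_max_s) {
  bind_windows(lapply(recordings, windows_from_recording,
                      window_len = window_len, stride = stride,
                      modality = modality, gap_max_s = gap_max_s))
}
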