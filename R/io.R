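#' @title On-disk interchange formats
#' @description Fixed CSV/JSON dialects for recordings, label timelines and
#'   placement rankings. Timestamps are seconds from recording start; CSVs
#'   carry a header row, comma separators and '.' decimals. Reals are written
#'   with 15 significant digits so round trips agree within 1e-12.
#' @name io
NULL

.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.15g", v)
  }, character(1))
  out
}

.write_csv_precise <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(num)) out[[j]] <- .fmt_num(df[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

har_log <- function(level, ...) {
  message(sprintf("[%s] %s", toupper(level), paste0(...)))
}

# ---- pose CSV ---------------------------------------------------------------

#' Write a pose sequence to CSV (wide dialect)
#'
#' Columns: `t_s`, then `<kp>_x, <kp>_y, <kp>_c` per keypoint. Missing
#' samples are written as empty fields.
#'
#' @param seq A `pose_sequence`.
#' @param path Output path.
#' @export
write_pose_csv <- function(seq, path) {
  cols <- list(t_s = seq$t)
  for (k in seq_along(seq$keypoints)) {
    kp <- seq$keypoints[k]
    cols[[paste0(kp, "_x")]] <- seq$x[, k]
    cols[[paste0(kp, "_y")]] <- seq$y[, k]
    cols[[paste0(kp, "_c")]] <- seq$conf[, k]
  }
  .write_csv_precise(as.data.frame(cols, check.names = FALSE), path)
  invisible(path)
}

#' Read a pose sequence from CSV
#'
#' Accepts the wide dialect (`t_s`, `<kp>_x/_y/_c`) or the long dialect
#' (`t_s, kp_name, x, y, confidence`, one row per keypoint per frame).
#'
#' @param path CSV path.
#' @return A `pose_sequence`.
#' @export
read_pose_csv <- function(path) {
  if (!file.exists(path)) stop("pose file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (all(c("t_s", "kp_name", "x", "y", "confidence") %in% names(df))) {
    kps <- unique(df$kp_name)
    ts <- sort(unique(df$t_s))
    x <- y <- conf <- matrix(NA_real_, length(ts), length(kps),
                             dimnames = list(NULL, kps))
    ti <- match(df$t_s, ts); ki <- match(df$kp_name, kps)
    idx <- cbind(ti, ki)
    x[idx] <- df$x; y[idx] <- df$y
    conf[idx] <- ifelse(is.na(df$confidence), 1, df$confidence)
    conf[is.na(conf)] <- 0
    return(pose_sequence(ts, x, y, conf, kps))
  }
  if (!"t_s" %in% names(df)) stop("pose CSV lacks a t_s column: ", path)
  xc <- grep("_x$", names(df), value = TRUE)
  kps <- sub("_x$", "", xc)
  if (length(kps) == 0L) stop("pose CSV has no keypoint columns: ", path)
  x <- as.matrix(df[, paste0(kps, "_x"), drop = FALSE])
  y <- as.matrix(df[, paste0(kps, "_y"), drop = FALSE])
  cc <- paste0(kps, "_c")
  conf <- if (all(cc %in% names(df))) as.matrix(df[, cc, drop = FALSE])
          else matrix(1, nrow(df), length(kps))
  conf[is.na(conf)] <- 0
  pose_sequence(df$t_s, x, y, conf, kps)
}

# ---- IMU CSV ----------------------------------------------------------------

#' Write an IMU sequence to CSV
#'
#' Columns: `t_s` then the 14 channels in [IMU_CHANNELS] order.
#'
#' @param seq An `imu_sequence`.
#' @param path Output path.
#' @export
write_imu_csv <- function(seq, path) {
  df <- data.frame(t_s = seq$t, seq$channels, check.names = FALSE)
  .write_csv_precise(df, path)
  invisible(path)
}

#' Read an IMU sequence from CSV
#' @param path CSV path.
#' @param location Body location tag to attach.
#' @return An `imu_sequence`.
#' @export
read_imu_csv <- function(path, location) {
  if (!file.exists(path)) stop("IMU file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(c("t_s", IMU_CHANNELS), names(df))
  if (length(missing))
    stop("IMU CSV ", path, " lacks column(s): ", paste(missing, collapse = ", "))
  imu_sequence(location, df$t_s, as.matrix(df[, IMU_CHANNELS, drop = FALSE]))
}

# ---- labels JSON ------------------------------------------------------------

#' Write a label timeline to JSON
#' @param labels A `label_timeline`.
#' @param path Output path.
#' @export
write_labels_json <- function(labels, path) {
  recs <- lapply(seq_len(nrow(labels)), function(i) {
    list(start_s = labels$start_s[i], end_s = labels$end_s[i],
         activity = labels$activity[i])
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a label timeline from JSON
#' @param path JSON path.
#' @return A `label_timeline`.
#' @export
read_labels_json <- function(path) {
  if (!file.exists(path)) stop("labels file not found: ", path)
  recs <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(recs) == 0L) return(label_timeline(numeric(0), numeric(0), character(0)))
  label_timeline(recs$start_s, recs$end_s, recs$activity)
}

# ---- recording manifest -----------------------------------------------------

#' Write a recording to a directory
#'
#' Produces `manifest.json` plus one IMU CSV per location, a pose CSV when
#' pose is present, and a labels JSON, all in the package dialects.
#'
#' @param rec A `recording`.
#' @param dir Output directory (created if absent).
#' @return Path of the written manifest, invisibly.
#' @export
write_recording <- function(rec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list(imu = list(), pose = NULL,
                labels = "labels.json")
  for (loc in names(rec$imus)) {
    fn <- paste0("imu_", loc, ".csv")
    write_imu_csv(rec$imus[[loc]], file.path(dir, fn))
    files$imu[[loc]] <- fn
  }
  if (!is.null(rec[["pose"]])) {
    files$pose <- "pose.csv"
    write_pose_csv(rec[["pose"]], file.path(dir, "pose.csv"))
  }
  write_labels_json(rec$labels, file.path(dir, "labels.json"))
  manifest <- list(
    recording_id = rec$recording_id, subject_id = rec$subject_id,
    sensor_locations = as.list(names(rec$imus)),
    pose_rate_hz = rec$pose_rate_hz, imu_rate_hz = rec$imu_rate_hz,
    files = files
  )
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(mp)
}

#' Load a recording from its manifest
#'
#' @param manifest_path Path to a `manifest.json` written by
#'   [write_recording()] (or hand-authored in the same dialect).
#' @return A `recording`; pose is `NULL` when the manifest lists no pose file
#'   (IMU-only mode).
#' @export
load_recording <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path)
  m <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  dir <- dirname(manifest_path)
  locs <- unlist(m$sensor_locations)
  if (length(locs) == 0L && is.null(m$files$pose))
    stop("manifest lists no sensor locations and no pose stream")
  if (length(locs) > 7L)
    stop("at most 7 sensor locations are supported, got ", length(locs))
  bad <- setdiff(locs, KEYPOINTS_12)
  if (length(bad))
    stop("unknown sensor location name(s): ", paste(bad, collapse = ", "))
  rate_p <- as.numeric(m$pose_rate_hz %||% 10)
  rate_i <- as.numeric(m$imu_rate_hz %||% 60)
  if (rate_p <= 0 || rate_i <= 0) stop("sampling rates must be positive")
  imus <- lapply(as.character(locs), function(loc) {
    fn <- m$files$imu[[loc]]
    if (is.null(fn)) stop("manifest lists no IMU file for location ", loc)
    read_imu_csv(file.path(dir, fn), loc)
  })
  names(imus) <- locs
  pose <- NULL
  if (!is.null(m$files$pose)) {
    pose <- read_pose_csv(file.path(dir, m$files$pose))
  }
  labels <- read_labels_json(file.path(dir, m$files$labels))
  recording(m$recording_id, m$subject_id, imus, pose, labels,
            pose_rate_hz = rate_p, imu_rate_hz = rate_i)
}

#' Load every recording found under a directory
#'
#' Scans `dir` recursively for `manifest.json` files.
#'
#' @param dir Directory of recording subdirectories.
#' @return List of `recording` objects.
#' @export
load_recordings <- function(dir) {
  mf <- list.files(dir, pattern = "^manifest\\.json$", recursive = TRUE,
                   full.names = TRUE)
  if (length(mf) == 0L) stop("no manifest.json found under ", dir)
  lapply(sort(mf), load_recording)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- ranking JSON -----------------------------------------------------------

#' Write a placement ranking to JSON
#'
#' One record per candidate subset: `{rank, locations, score, size,
#' best_of_size}`.
#'
#' @param ranking A `placement_ranking`.
#' @param path Output path.
#' @export
write_ranking <- function(ranking, path) {
  if (nrow(ranking) == 0L) stop("ranking must be non-empty")
  recs <- lapply(seq_len(nrow(ranking)), function(i) {
    list(rank = ranking$rank[i],
         locations = as.list(ranking$subset[[i]]),
         score = ranking$score[i],
         size = ranking$size[i],
         best_of_size = ranking$best_of_size[i])
  })
  jsonlite::write_json(
    list(n_activities = attr(ranking, "n_activities"),
         folds = attr(ranking, "folds"),
         ranking = recs),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a placement ranking from JSON
#' @param path JSON path written by [write_ranking()].
#' @return A `placement_ranking`.
#' @export
read_ranking <- function(path) {
  if (!file.exists(path)) stop("ranking file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  recs <- obj$ranking
  df <- data.frame(
    rank = vapply(recs, function(r) as.integer(r$rank), integer(1)),
    size = vapply(recs, function(r) as.integer(r$size), integer(1)),
    score = vapply(recs, function(r) as.numeric(r$score), numeric(1)),
    best_of_size = vapply(recs, function(r) isTRUE(r$best_of_size), logical(1)),
    stringsAsFactors = FALSE
  )
  df$subset <- lapply(recs, function(r) unlist(r$locations))
  df <- df[, c("rank", "subset", "size", "score", "best_of_size")]
  structure(df, class = c("placement_ranking", "data.frame"),
            n_activities = obj$n_activities, folds = obj$folds)
}

# ---- windowed dataset container --------------------------------------------

#' Write a windowed dataset to a CSV + JSON container
#'
#' `<prefix>.csv` holds the window contents in long form (`window`, `row`,
#' then one column per feature); `<prefix>.json` holds labels, provenance,
#' feature names and the pose-column mask.
#'
#' @param dataset A `windowed_dataset`.
#' @param prefix Output path prefix.
#' @return The prefix, invisibly.
#' @export
write_windows <- function(dataset, prefix) {
  n <- n_windows(dataset)
  d <- dim(dataset$X)
  flat <- matrix(aperm(dataset$X, c(2L, 1L, 3L)), n * d[2L], d[3L])
  df <- data.frame(window = rep(seq_len(n), each = d[2L]),
                   row = rep(seq_len(d[2L]), times = n))
  df <- cbind(df, as.data.frame(flat))
  names(df) <- c("window", "row", dataset$feature_names)
  .write_csv_precise(df, paste0(prefix, ".csv"))
  jsonlite::write_json(
    list(window_len = d[2L], n_features = d[3L],
         labels = dataset$labels, subject_id = dataset$subject_id,
         recording_id = dataset$recording_id,
         feature_names = dataset$feature_names,
         pose_cols = dataset$pose_cols),
    paste0(prefix, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(prefix)
}

#' Read a windowed dataset written by [write_windows()]
#' @param prefix Path prefix.
#' @return A `windowed_dataset`.
#' @export
read_windows <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(paste0(prefix, ".csv"), check.names = FALSE)
  n <- length(meta$labels); L <- meta$window_len; Fn <- meta$n_features
  flat <- as.matrix(df[, meta$feature_names, drop = FALSE])
  X <- aperm(array(flat, c(L, n, Fn)), c(2L, 1L, 3L))
  .windowed_dataset(X, meta$labels, meta$subject_id, meta$recording_id,
                    meta$feature_names, meta$pose_cols)
}
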