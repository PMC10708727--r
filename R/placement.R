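#' @title Cosine-distance sensor placement ranking
#' @description Phases 2-3 of the placement algorithm. Each candidate
#'   keypoint (or subset of keypoints) is treated as a virtual accelerometer:
#'   its centralized positional trace during activity i is flattened into an
#'   activity vector A_i, and the placement's discriminative power is
#'
#'   \deqn{D = \sum_{i<j} | 1 - A_i \cdot A_j / (\|A_i\| \|A_j\|) |}
#'
#'   the sum of absolute cosine distances over all activity pairs. Higher D
#'   means the placement separates the activities better. Multi-sensor
#'   combinations are scored by concatenating the per-keypoint vectors, and
#'   the metric is cross-validated over contiguous temporal folds.
#' @name placement
NULL

#' Build an activity vector from a centralized pose series
#'
#' For each keypoint in `keypoints` order, the first `T` frames' coordinates
#' are flattened time-major as (x1, y1, ..., xT, yT); keypoint blocks are then
#' concatenated, giving length `2 * T * |keypoints|`. When a label timeline is
#' supplied, frames are first restricted to the activity's labeled intervals;
#' frames with any missing candidate coordinate are dropped before truncation.
#'
#' @param seq A centralized `pose_sequence`.
#' @param keypoints Ordered keypoint subset.
#' @param activity Activity name (recorded on the result).
#' @param T_len Number of frames to use.
#' @param labels Optional `label_timeline` to restrict frames by.
#' @return Object of class `activity_vector` (numeric vector with attributes
#'   `keypoints` and `activity`).
#' @export
build_activity_vector <- function(seq, keypoints, activity, T_len,
                                  labels = NULL) {
  if (T_len < 1L) stop("T_len must be >= 1")
  fr <- .activity_frames(seq, keypoints, activity, labels)
  if (nrow(fr) < T_len) {
    stop(sprintf(
      "insufficient data for activity '%s': %d frames available, %d required",
      activity, nrow(fr), T_len))
  }
  .vector_from_frames(fr[seq_len(T_len), , drop = FALSE], keypoints, activity)
}

# frames x (2*|keypoints|) matrix of valid candidate coordinates,
# columns interleaved (x, y) per keypoint in subset order
.activity_frames <- function(seq, keypoints, activity, labels = NULL) {
  keep <- rep(TRUE, length(seq$t))
  if (!is.null(labels)) {
    iv <- labels[labels$activity == activity, , drop = FALSE]
    keep <- rep(FALSE, length(seq$t))
    for (r in seq_len(nrow(iv))) {
      keep <- keep | (seq$t >= iv$start_s[r] & seq$t < iv$end_s[r])
    }
  }
  bad <- setdiff(keypoints, seq$keypoints)
  if (length(bad)) stop("keypoint(s) absent from series: ",
                        paste(bad, collapse = ", "))
  m <- matrix(0, sum(keep), 2L * length(keypoints))
  for (k in seq_along(keypoints)) {
    m[, 2L * k - 1L] <- seq$x[keep, keypoints[k]]
    m[, 2L * k] <- seq$y[keep, keypoints[k]]
  }
  m[stats::complete.cases(m), , drop = FALSE]
}

.vector_from_frames <- function(fr, keypoints, activity) {
  blocks <- lapply(seq_along(keypoints), function(k) {
    as.vector(t(fr[, c(2L * k - 1L, 2L * k), drop = FALSE]))
  })
  structure(unlist(blocks), class = "activity_vector",
            keypoints = as.character(keypoints), activity = activity)
}

#' Absolute cosine distance between two activity vectors
#'
#' `|1 - cos(a, b)|`, in [0, 2]. Zero-norm vectors are rejected: a
#' motionless, exactly-zero trace has no direction and is not rankable.
#'
#' @param a,b Equal-length numeric vectors.
#' @return The pair term, a scalar in [0, 2].
#' @export
pair_term <- function(a, b) {
  if (length(a) != length(b)) stop("activity vectors must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("degenerate input: zero-norm activity vector")
  abs(1 - sum(a * b) / (na * nb))
}

#' Activity-pair dissimilarity score D for one placement
#'
#' Sums [pair_term()] over all n(n-1)/2 unordered activity pairs.
#'
#' @param vectors List of n >= 2 `activity_vector`s for the same keypoint
#'   subset, one per distinct activity.
#' @return Object of class `placement_score` with fields `subset`, `score`,
#'   `n_activities`, `folds`.
#' @export
compute_D <- function(vectors) {
  n <- length(vectors)
  if (n < 2L) stop("need at least 2 activity vectors")
  acts <- vapply(vectors, function(v) attr(v, "activity") %||% NA_character_,
                 character(1))
  if (!anyNA(acts) && anyDuplicated(acts))
    stop("duplicate activity among vectors")
  lens <- lengths(vectors)
  if (length(unique(lens)) != 1L)
    stop("all activity vectors must have equal length")
  score <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) score <- score + pair_term(vectors[[i]], vectors[[j]])
  }
  structure(list(subset = attr(vectors[[1L]], "keypoints"),
                 score = score, n_activities = n, folds = 1L),
            class = "placement_score")
}

#' @export
print.placement_score <- function(x, ...) {
  cat(sprintf("<placement_score> {%s}: D = %.6g over %d activities (%d fold%s)\n",
              paste(x$subset, collapse = ", "), x$score, x$n_activities,
              x$folds, if (x$folds == 1L) "" else "s"))
  invisible(x)
}

#' Cross-validated placement score
#'
#' Each activity's valid frame trace is split into `folds` contiguous blocks
#' of `T_fold` frames; [compute_D()] is evaluated at each fold index and the
#' score is the fold mean.
#'
#' @param seq A centralized `pose_sequence`, or a pre-extracted named list of
#'   per-activity frame matrices as produced internally.
#' @param subset Keypoint subset to score.
#' @param activities Activity names (all must be available).
#' @param folds Number of contiguous folds (>= 1).
#' @param T_fold Frames per fold.
#' @param labels Optional `label_timeline` when `seq` is a `pose_sequence`.
#' @return A `placement_score` with `folds` recorded.
#' @export
compute_D_crossvalidated <- function(seq, subset, activities, folds, T_fold,
                                     labels = NULL) {
  if (folds < 1L) stop("folds must be >= 1")
  if (T_fold < 1L) stop("T_fold must be >= 1")
  frames <- if (inherits(seq, "pose_sequence")) {
    stats::setNames(lapply(activities, function(a)
      .activity_frames(seq, subset, a, labels)), activities)
  } else {
    lapply(seq[activities], function(fr) {
      cols <- as.vector(rbind(2L * match(subset, attr(seq, "keypoints")) - 1L,
                              2L * match(subset, attr(seq, "keypoints"))))
      fr[, cols, drop = FALSE]
    })
  }
  need <- folds * T_fold
  avail <- vapply(frames, nrow, integer(1))
  if (any(avail < need)) {
    short <- names(frames)[avail < need][1L]
    stop(sprintf(
      "insufficient data for activity '%s': %d frames available, %d required",
      short, avail[[short]], need))
  }
  per_fold <- vapply(seq_len(folds), function(f) {
    idx <- ((f - 1L) * T_fold + 1L):(f * T_fold)
    vecs <- lapply(activities, function(a)
      .vector_from_frames(frames[[a]][idx, , drop = FALSE], subset, a))
    compute_D(vecs)$score
  }, numeric(1))
  structure(list(subset = as.character(subset), score = mean(per_fold),
                 n_activities = length(activities), folds = as.integer(folds),
                 fold_scores = per_fold),
            class = "placement_score")
}

#' Enumerate candidate subsets
#'
#' All non-empty subsets of size `<= max_size`, ordered by size and then
#' lexicographically in candidate order. With 5 candidates and `max_size = 5`
#' this yields 31 subsets.
#'
#' @param candidates A `candidate_set` or character vector.
#' @param max_size Largest subset size.
#' @return List of character vectors.
#' @export
enumerate_combinations <- function(candidates, max_size = length(candidates)) {
  candidates <- as.character(candidates)
  m <- length(candidates)
  if (max_size < 1L || max_size > m)
    stop("max_size must be between 1 and ", m)
  out <- list()
  for (s in seq_len(max_size)) {
    cmb <- utils::combn(m, s, simplify = FALSE)
    out <- c(out, lapply(cmb, function(i) candidates[i]))
  }
  out
}

#' Rank sensor placements over a set of recordings
#'
#' Full pipeline: each recording's pose stream is consolidated, centralized
#' and restricted to the candidates; per-activity frame traces are pooled
#' across recordings; every enumerated subset is scored with the
#' cross-validated D metric; subsets are ranked by descending score, ties
#' broken by fewer sensors then canonical order. The per-size optimum is
#' flagged in the result.
#'
#' @param recordings A `recording` or list of recordings with pose streams.
#' @param candidates Candidate locations (default wrists, pelvis, ankles).
#' @param max_size Largest subset size to consider.
#' @param folds Contiguous folds for cross-validation (default 5).
#' @param min_len Minimum frames required per activity (default 500, i.e.
#'   50 s at 10 Hz).
#' @param T_fold Frames per fold; default uses `min(3000, available)` frames
#'   total per activity (5 min at 10 Hz when available).
#' @param confidence_threshold Confidence cut-off for missingness.
#' @return Object of class `placement_ranking`: a data frame with columns
#'   `rank`, `subset` (list), `size`, `score`, `best_of_size`.
#' @export
rank_placements <- function(recordings, candidates = candidate_set(),
                            max_size = length(candidates), folds = 5L,
                            min_len = har_defaults()$min_placement_frames,
                            T_fold = NULL,
                            confidence_threshold = har_defaults()$confidence_threshold) {
  if (inherits(recordings, "recording")) recordings <- list(recordings)
  candidates <- as.character(candidates)
  # pool per-activity candidate frames across recordings
  frames <- list()
  for (rec in recordings) {
    seq <- preprocess_pose(rec, candidates, confidence_threshold)
    for (a in unique(rec$labels$activity)) {
      fr <- .activity_frames(seq, candidates, a, rec$labels)
      frames[[a]] <- rbind(frames[[a]], fr)
    }
  }
  activities <- sort(names(frames))
  if (length(activities) < 2L) stop("need at least 2 activities to rank")
  avail <- vapply(frames, nrow, integer(1))[activities]
  if (any(avail < min_len)) {
    short <- activities[avail < min_len][1L]
    stop(sprintf(paste0(
      "activity '%s' has %d frames; each activity requires a minimum ",
      "sequence length of %d data points"), short, avail[[short]], min_len))
  }
  corpus <- min(har_defaults()$placement_corpus_frames, min(avail))
  if (is.null(T_fold)) T_fold <- corpus %/% folds
  frames <- structure(frames, keypoints = candidates)
  subsets <- enumerate_combinations(candidates, max_size)
  scores <- vapply(subsets, function(s) {
    compute_D_crossvalidated(frames, s, activities, folds, T_fold)$score
  }, numeric(1))
  sizes <- lengths(subsets)
  # tie-break: higher score, fewer sensors, canonical lexicographic order;
  # scores equal within 1e-12 count as tied (cosine round-off)
  canon <- vapply(subsets, function(s)
    paste(sprintf("%02d", match(s, candidates)), collapse = ""), character(1))
  ord <- order(-round(scores / 1e-12) * 1e-12, sizes, canon)
  df <- data.frame(rank = seq_along(ord), size = sizes[ord],
                   score = scores[ord], stringsAsFactors = FALSE)
  df$subset <- subsets[ord]
  df$best_of_size <- !duplicated(df$size)
  df <- df[, c("rank", "subset", "size", "score", "best_of_size")]
  structure(df, class = c("placement_ranking", "data.frame"),
            n_activities = length(activities), folds = as.integer(folds),
            T_fold = as.integer(T_fold))
}

#' @export
print.placement_ranking <- function(x, n = 10L, ...) {
  cat(sprintf("<placement_ranking> %d subsets, %d activities, %d folds\n",
              nrow(x), attr(x, "n_activities"), attr(x, "folds")))
  top <- utils::head(x, n)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  %2d. %-45s D = %.6g%s\n", top$rank[i],
                paste(top$subset[[i]], collapse = "+"), top$score[i],
                if (top$best_of_size[i]) sprintf("  [best with %d]", top$size[i]) else ""))
  }
  if (nrow(x) > n) cat("  ...\n")
  invisible(x)
}

#' Best subset of a given size from a ranking
#' @param ranking A `placement_ranking`.
#' @param size Subset size.
#' @return Character vector of locations.
#' @export
best_subset_of_size <- function(ranking, size) {
  rows <- ranking[ranking$size == size, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no subsets of size ", size, " in ranking")
  rows$subset[[which.min(rows$rank)]]
}
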