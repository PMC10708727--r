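#' @title Evaluation protocols and metrics
#' @description The three cross-validation schemes used for HAR window
#'   classifiers (shuffled k-fold over windows, leave-recordings-out at a
#'   target train ratio, leave-one-subject-out), the categorical
#'   cross-entropy loss, accuracy / macro-F1 / confusion-matrix reports, and
#'   per-subject per-activity time statistics.
#' @name evaluation
NULL

.split_plan <- function(scheme, folds, seed = NA_integer_) {
  structure(list(scheme = scheme, folds = folds, seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %s: %d fold(s)\n", x$scheme, length(x$folds)))
  invisible(x)
}

#' Shuffled k-fold split over windows
#'
#' Window indices are shuffled (seeded) and partitioned into k near-equal
#' folds; each fold serves once as the test set.
#'
#' @param dataset A `windowed_dataset`.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return A `split_plan` with `k` folds of `(train, test)` index vectors.
#' @export
kfold_split <- function(dataset, k = 5L, seed = 1L) {
  n <- n_windows(dataset)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k exceeds the number of windows (", n, ")")
  idx <- with_seed(seed, sample.int(n))
  grp <- rep(seq_len(k), times = diff(floor(n * (0:k) / k)))
  folds <- lapply(seq_len(k), function(f) {
    test <- sort(idx[grp == f])
    list(train = setdiff(seq_len(n), test), test = test)
  })
  .split_plan("kfold", folds, seed)
}

#' Leave-recordings-out split
#'
#' Whole recordings are assigned to the training side, in seeded random
#' order, until the training window count first reaches `train_ratio` of the
#' total; the rest is the test side. No recording is ever split across sides.
#'
#' @param dataset A `windowed_dataset`.
#' @param train_ratio Target train fraction (default 0.8).
#' @param seed Integer seed.
#' @return A single-fold `split_plan`.
#' @export
leave_recordings_out_split <- function(dataset, train_ratio = 0.8, seed = 1L) {
  recs <- unique(dataset$recording_id)
  if (length(recs) < 2L) stop("need at least 2 recordings")
  ord <- with_seed(seed, sample(recs))
  n <- n_windows(dataset)
  train_recs <- character(0)
  count <- 0L
  for (r in ord[-length(ord)]) {  # the last recording always stays testable
    if (count >= train_ratio * n) break
    train_recs <- c(train_recs, r)
    count <- count + sum(dataset$recording_id == r)
  }
  if (count < train_ratio * n) {
    har_log("warn", sprintf(
      "train side holds %d/%d windows, short of the %.0f%% target (whole recordings are never split)",
      count, n, 100 * train_ratio))
  }
  train <- which(dataset$recording_id %in% train_recs)
  .split_plan("leave_recordings_out",
              list(list(train = train, test = setdiff(seq_len(n), train))),
              seed)
}

#' Leave-one-subject-out split
#'
#' One fold per subject; that subject's windows form the entire test set and
#' appear nowhere in the training set.
#'
#' @param dataset A `windowed_dataset`.
#' @return A `split_plan` with one fold per subject.
#' @export
loso_split <- function(dataset) {
  subs <- unique(dataset$subject_id)
  if (length(subs) < 2L) stop("need at least 2 subjects")
  n <- n_windows(dataset)
  folds <- lapply(subs, function(s) {
    test <- which(dataset$subject_id == s)
    list(train = setdiff(seq_len(n), test), test = test, subject = s)
  })
  .split_plan("leave_one_subject_out", folds)
}

#' Categorical cross-entropy of raw class scores
#'
#' `-log(softmax(scores)[target])`, computed with the log-sum-exp trick.
#' Invariant under adding a constant to all scores; minimized when the target
#' class has the largest score.
#'
#' @param scores Numeric vector of C >= 2 raw class scores (logits).
#' @param target Index of the true class (1-based).
#' @return Non-negative scalar loss.
#' @export
cross_entropy <- function(scores, target) {
  if (length(scores) < 2L) stop("need at least 2 classes")
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (target < 1L || target > length(scores)) stop("invalid target class")
  .ce_batch(matrix(scores, 1L), target)
}

# shared implementation: rows of scores, vector of 1-based targets
.ce_batch <- function(scores, targets) {
  m <- apply(scores, 1L, max)
  lse <- m + log(rowSums(exp(scores - m)))
  sp <- scores[cbind(seq_len(nrow(scores)), targets)]
  mean(lse - sp)
}

.softmax_rows <- function(scores) {
  m <- apply(scores, 1L, max)
  e <- exp(scores - m)
  e / rowSums(e)
}

#' Classification report: accuracy, macro-F1, confusion matrix
#'
#' Macro-F1 is the unweighted mean of per-class F1 over classes present in
#' the truth; the confusion matrix is row-normalized (rows = truth). The
#' print method suppresses cells below 0.05.
#'
#' @param predictions Character vector of predicted labels.
#' @param labels Character vector of true labels, same length.
#' @param classes Class set; defaults to the union of both. A prediction or
#'   label outside it is an error.
#' @return Object of class `eval_report` with fields `accuracy`, `macro_f1`,
#'   `confusion`, `counts`, `n`.
#' @export
evaluate <- function(predictions, labels, classes = NULL) {
  if (length(predictions) != length(labels))
    stop("predictions and labels must have equal length")
  if (is.null(classes)) classes <- sort(unique(c(predictions, labels)))
  bad <- setdiff(c(predictions, labels), classes)
  if (length(bad)) stop("label(s) outside class set: ",
                        paste(unique(bad), collapse = ", "))
  p <- factor(predictions, levels = classes)
  y <- factor(labels, levels = classes)
  counts <- table(truth = y, predicted = p)
  acc <- mean(predictions == labels)
  f1 <- vapply(classes, function(cl) {
    tp <- sum(predictions == cl & labels == cl)
    fp <- sum(predictions == cl & labels != cl)
    fn <- sum(predictions != cl & labels == cl)
    if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  present <- classes %in% labels
  macro_f1 <- mean(f1[present])
  rs <- rowSums(counts)
  confusion <- counts / ifelse(rs == 0, 1, rs)  # absent-class rows stay 0
  structure(list(accuracy = acc, macro_f1 = macro_f1,
                 confusion = unclass(confusion), counts = unclass(counts),
                 per_class_f1 = f1, n = length(labels)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, suppress_below = 0.05, ...) {
  cat(sprintf("<eval_report> n = %d, accuracy = %.3f, macro F1 = %.3f\n",
              x$n, x$accuracy, x$macro_f1))
  cm <- x$confusion
  shown <- ifelse(cm < suppress_below, "", sprintf("%.2f", cm))
  dim(shown) <- dim(cm); dimnames(shown) <- dimnames(cm)
  print(shown, quote = FALSE)
  invisible(x)
}

#' Aggregate per-fold reports as mean and sd
#'
#' @param reports List of `eval_report`s (one per fold).
#' @return List with `accuracy` and `macro_f1`, each `c(mean, sd)`, plus the
#'   fold reports.
#' @export
aggregate_reports <- function(reports) {
  acc <- vapply(reports, function(r) r$accuracy, numeric(1))
  f1 <- vapply(reports, function(r) r$macro_f1, numeric(1))
  list(accuracy = c(mean = mean(acc), sd = stats::sd(acc)),
       macro_f1 = c(mean = mean(f1), sd = stats::sd(f1)),
       folds = reports)
}

#' Per-subject per-activity time statistics
#'
#' Sums labeled seconds per (subject, activity) over recordings, with row and
#' column totals, the kind of dashboard summary used to compare how much time
#' each person spent on each activity. Overlapping label intervals within a
#' recording are a validation error.
#'
#' @param recordings A `recording` or list of recordings.
#' @return Numeric matrix (subjects + "total") x (activities + "total") of
#'   seconds, class `activity_time_summary`.
#' @export
activity_time_summary <- function(recordings) {
  if (inherits(recordings, "recording")) recordings <- list(recordings)
  for (rec in recordings) .check_label_overlap(rec$labels)
  subs <- sort(unique(vapply(recordings, function(r) r$subject_id, character(1))))
  acts <- sort(unique(unlist(lapply(recordings, function(r) r$labels$activity))))
  m <- matrix(0, length(subs), max(length(acts), 1L),
              dimnames = list(subs, if (length(acts)) acts else "none"))
  for (rec in recordings) {
    lb <- rec$labels
    for (i in seq_len(nrow(lb))) {
      m[rec$subject_id, lb$activity[i]] <-
        m[rec$subject_id, lb$activity[i]] + (lb$end_s[i] - lb$start_s[i])
    }
  }
  out <- rbind(cbind(m, total = rowSums(m)),
               total = c(colSums(m), sum(m)))
  structure(out, class = c("activity_time_summary", class(out)))
}

#' @export
print.activity_time_summary <- function(x, ...) {
  cat("<activity_time_summary> labeled seconds per subject and activity\n")
  print(round(unclass(x), 1))
  invisible(x)
}

#' Subset a windowed dataset by window indices
#' @param dataset A `windowed_dataset`.
#' @param idx Integer indices.
#' @return A `windowed_dataset`.
#' @export
subset_windows <- function(dataset, idx) {
  .windowed_dataset(dataset$X[idx, , , drop = FALSE], dataset$labels[idx],
                    dataset$subject_id[idx], dataset$recording_id[idx],
                    dataset$feature_names, dataset$pose_cols)
}
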