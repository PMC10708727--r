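test_that("k-fold plans partition the windows into near-equal shuffled folds", {
  ds <- fake_dataset(10)
  plan <- kfold_split(ds, k = 5, seed = 3)
  expect_length(plan$folds, 5L)
  tests <- lapply(plan$folds, `[[`, "test")
  expect_true(all(lengths(tests) == 2L))
  expect_identical(sort(unlist(tests)), 1:10)
  for (f in plan$folds) {
    expect_length(intersect(f$train, f$test), 0L)
    expect_identical(sort(c(f$train, f$test)), 1:10)
  }
  expect_identical(kfold_split(ds, 5, seed = 3), plan)
  expect_false(identical(kfold_split(ds, 5, seed = 4), plan))
  expect_error(kfold_split(ds, 11), "exceeds")
  expect_error(kfold_split(ds, 1), "k must be")
})

test_that("leave-recordings-out never splits a recording across sides", {
  ds <- fake_dataset(60, n_subjects = 3, recs_per_subject = 3, seed = 8)
  plan <- leave_recordings_out_split(ds, 0.8, seed = 1)
  f <- plan$folds[[1]]
  tr_recs <- unique(ds$recording_id[f$train])
  te_recs <- unique(ds$recording_id[f$test])
  expect_length(intersect(tr_recs, te_recs), 0L)
  expect_gte(length(f$train), 0.8 * 60 - max(table(ds$recording_id)))
  expect_gt(length(f$test), 0L)
  # ratio 0.5 with 2 equal recordings gives a 1/1 split
  ds2 <- fake_dataset(20, n_subjects = 1, recs_per_subject = 2, seed = 2)
  # force exactly equal halves
  ds2$recording_id <- rep(c("r1", "r2"), each = 10)
  p2 <- leave_recordings_out_split(ds2, 0.5, seed = 1)
  expect_identical(lengths(p2$folds[[1]])[c("train", "test")],
                   c(train = 10L, test = 10L))
  ds1 <- ds2; ds1$recording_id <- rep("r1", 20)
  expect_error(leave_recordings_out_split(ds1), "at least 2 recordings")
})

test_that("LOSO holds each subject out exactly once", {
  ds <- fake_dataset(40, n_subjects = 4, seed = 5)
  plan <- loso_split(ds)
  expect_length(plan$folds, 4L)
  for (f in plan$folds) {
    expect_length(intersect(unique(ds$subject_id[f$train]),
                            unique(ds$subject_id[f$test])), 0L)
    expect_length(unique(ds$subject_id[f$test]), 1L)
  }
  expect_identical(sort(unlist(lapply(plan$folds, `[[`, "test"))), 1:40)
  ds1 <- ds; ds1$subject_id <- rep("only", 40)
  expect_error(loso_split(ds1), "at least 2 subjects")
})

test_that("cross-entropy matches the softmax definition", {
  expect_equal(cross_entropy(rep(0, 13), 1), log(13), tolerance = 1e-9)
  expect_equal(cross_entropy(rep(7.3, 13), 5), log(13), tolerance = 1e-9)
  # direct softmax evaluation oracle
  sc <- c(2, 0, 0)
  expect_equal(cross_entropy(sc, 1), -log(exp(2) / sum(exp(sc))),
               tolerance = 1e-12)
  expect_equal(cross_entropy(sc, 1), 0.2395, tolerance = 1e-3)
  # shift invariance
  set.seed(2)
  for (i in 1:10) {
    s <- rnorm(6); k <- sample(6, 1); sh <- runif(1, -50, 50)
    expect_equal(cross_entropy(s + sh, k), cross_entropy(s, k),
                 tolerance = 1e-9)
    expect_gte(cross_entropy(s, k), 0)
  }
  # minimized at the argmax class
  s <- c(0.1, 3, -1)
  losses <- vapply(1:3, function(k) cross_entropy(s, k), numeric(1))
  expect_identical(which.min(losses), 2L)
  expect_error(cross_entropy(c(1, Inf), 1), "finite")
  expect_error(cross_entropy(c(1, 2), 3), "target")
  expect_error(cross_entropy(5, 1), "at least 2")
})

test_that("classification reports match hand-computed metrics", {
  y <- c("a", "a", "b", "b")
  expect_equal(evaluate(y, y)$accuracy, 1)
  expect_equal(evaluate(y, y)$macro_f1, 1)
  expect_equal(unclass(evaluate(y, y)$confusion), diag(2),
               ignore_attr = TRUE)
  # all predictions one class over balanced 2-class truth
  r <- evaluate(rep("a", 4), y)
  expect_equal(r$accuracy, 0.5)
  # 3-class worked case:
  # truth  a a a b b c ; pred a b a b c c
  # class a: tp=2 fp=0 fn=1 -> F1 = 4/5
  # class b: tp=1 fp=1 fn=1 -> F1 = 1/2
  # class c: tp=1 fp=1 fn=0 -> F1 = 2/3
  truth <- c("a", "a", "a", "b", "b", "c")
  pred <- c("a", "b", "a", "b", "c", "c")
  r3 <- evaluate(pred, truth)
  expect_equal(r3$accuracy, 4 / 6)
  expect_equal(unname(r3$per_class_f1), c(4 / 5, 1 / 2, 2 / 3))
  expect_equal(r3$macro_f1, mean(c(4 / 5, 1 / 2, 2 / 3)))
  expect_equal(unname(rowSums(r3$confusion)), c(1, 1, 1))
  # a class absent from the truth is excluded from macro-F1
  r4 <- evaluate(c("a", "b"), c("a", "a"), classes = c("a", "b", "c"))
  expect_equal(r4$macro_f1, 2 / 3)  # only class "a" occurs in the truth
  expect_equal(unname(rowSums(r4$confusion)), c(1, 0, 0))
  expect_error(evaluate(c("a", "z"), c("a", "a"), classes = c("a", "b")),
               "outside class set")
  expect_error(evaluate("a", c("a", "b")), "equal length")
})

test_that("report rendering suppresses near-zero confusion cells", {
  set.seed(4)
  truth <- rep(c("a", "b"), each = 50)
  pred <- truth
  pred[1] <- "b"  # one confusion of 0.02 < 0.05
  out <- paste(utils::capture.output(print(evaluate(pred, truth))),
               collapse = "\n")
  expect_false(grepl("0\\.02", out))
  expect_true(grepl("0\\.98", out))
})

test_that("activity time statistics sum labeled seconds with totals", {
  p <- tiny_protocol(segment_duration_s = 60)
  r1 <- simulate_recording(p, "s1", data.frame(activity = "feeding",
                                               duration_s = 120),
                           with_imu = FALSE)
  r2 <- simulate_recording(p, "s2", p$activities, with_imu = FALSE,
                           recording_id = "s2_rec1")
  s <- activity_time_summary(list(r1, r2))
  expect_equal(s["s1", "feeding"], 120)
  expect_equal(s["s2", "make_bed"], 60)
  expect_equal(s["total", "total"],
               labeled_duration(r1$labels) + labeled_duration(r2$labels))
  expect_equal(unname(s[, "total"][c("s1", "s2")]),
               unname(rowSums(s[c("s1", "s2"), c("feeding", "make_bed")])))
  # overlapping intervals are a validation error
  bad <- r1
  bad$labels <- label_timeline(c(0, 50), c(60, 100), c("feeding", "make_bed"))
  expect_error(activity_time_summary(bad), "overlapping")
})

test_that("per-fold aggregation reports mean and sd", {
  reports <- list(evaluate(c("a", "b"), c("a", "b")),
                  evaluate(c("a", "a"), c("a", "b")))
  agg <- aggregate_reports(reports)
  expect_equal(unname(agg$accuracy["mean"]), 0.75)
  expect_equal(unname(agg$accuracy["sd"]), stats::sd(c(1, 0.5)))
})
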