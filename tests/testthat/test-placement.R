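# independent brute-force reference: direct dot/norm double loop
oracle_D <- function(vectors) {
  s <- 0
  n <- length(vectors)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- as.numeric(vectors[[i]]); b <- as.numeric(vectors[[j]])
      s <- s + abs(1 - (a %*% b) / (sqrt(sum(a * a)) * sqrt(sum(b * b))))
    }
  }
  as.numeric(s)
}

av <- function(values, activity = "a", keypoints = "k") {
  structure(values, class = "activity_vector",
            keypoints = keypoints, activity = activity)
}

test_that("activity vectors are laid out time-major per keypoint block", {
  # one keypoint at (0.1, 0.2) then (0.3, 0.4) flattens to (x1,y1,x2,y2)
  seq1 <- pose_sequence(0:1, cbind(k1 = c(0.1, 0.3)), cbind(k1 = c(0.2, 0.4)))
  v <- build_activity_vector(seq1, "k1", "walk", 2)
  expect_equal(as.numeric(v), c(0.1, 0.2, 0.3, 0.4))
  # two keypoints, T = 1: first keypoint's pair first, length 4
  seq2 <- pose_sequence(0, cbind(k1 = 0.1, k2 = 0.5),
                        cbind(k1 = 0.2, k2 = 0.6))
  v2 <- build_activity_vector(seq2, c("k1", "k2"), "walk", 1)
  expect_equal(as.numeric(v2), c(0.1, 0.2, 0.5, 0.6))
  # a subset vector equals the concatenation of its single-keypoint vectors
  seq3 <- pose_sequence(0:3, matrix(runif(8), 4, 2,
                                    dimnames = list(NULL, c("right_wrist", "pelvis"))),
                        matrix(runif(8), 4, 2,
                               dimnames = list(NULL, c("right_wrist", "pelvis"))))
  both <- build_activity_vector(seq3, c("right_wrist", "pelvis"), "walk", 4)
  w <- build_activity_vector(seq3, "right_wrist", "walk", 4)
  p <- build_activity_vector(seq3, "pelvis", "walk", 4)
  expect_equal(as.numeric(both), c(as.numeric(w), as.numeric(p)))
  expect_length(both, 2 * 4 * 2)
})

test_that("insufficient frames are reported with the available count", {
  seq1 <- pose_sequence(0:2, cbind(k1 = runif(3)), cbind(k1 = runif(3)))
  expect_error(build_activity_vector(seq1, "k1", "walk", 10),
               "3 frames available, 10 required")
  lb <- label_timeline(0, 1.5, "walk")
  v <- build_activity_vector(seq1, "k1", "walk", 2, labels = lb)
  expect_length(v, 4L)  # only frames inside the labeled interval
})

test_that("the pair term is the absolute cosine distance", {
  x <- c(0.3, -1.2, 4.5)
  expect_equal(pair_term(x, x), 0)
  expect_equal(pair_term(c(1, 0), c(0, 1)), 1)
  expect_equal(pair_term(c(1, 0), c(-1, 0)), 2)
  expect_error(pair_term(c(0, 0), c(1, 0)), "zero-norm")
  expect_error(pair_term(c(1, 0), c(1, 0, 0)), "equal length")
})

test_that("compute_D matches the analytic cases and the brute-force oracle", {
  e <- function(i) { v <- rep(0, 3); v[i] <- 1; v }
  orth <- lapply(1:3, function(i) av(e(i), letters[i]))
  expect_equal(compute_D(orth)$score, 3)
  same <- lapply(1:4, function(i) av(c(1, 2, 3), letters[i]))
  expect_equal(compute_D(same)$score, 0)
  anti <- list(av(c(1, 0), "a"), av(c(-1, 0), "b"))
  expect_equal(compute_D(anti)$score, 2)
  # oracle equivalence on random instances
  set.seed(99)
  for (rep in 1:100) {
    n <- sample(2:6, 1)
    len <- sample(2:50, 1)
    vecs <- lapply(seq_len(n), function(i)
      av(stats::rnorm(len), sprintf("act%d", i)))
    expect_equal(compute_D(vecs)$score, oracle_D(vecs), tolerance = 1e-9)
  }
  expect_error(compute_D(same[1]), "at least 2")
  expect_error(compute_D(list(av(1:2, "a"), av(1:2, "a"))), "duplicate")
})

test_that("scores are scale- and permutation-invariant and bounded", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(2:5, 1)
    vecs <- lapply(seq_len(n), function(i) av(stats::rnorm(12), letters[i]))
    d0 <- compute_D(vecs)$score
    scaled <- vecs
    scaled[[1]] <- av(scaled[[1]] * runif(1, 0.1, 50), "a")
    expect_equal(compute_D(scaled)$score, d0, tolerance = 1e-9)
    expect_equal(compute_D(rev(vecs))$score, d0, tolerance = 1e-12)
    expect_gte(d0, 0)
    expect_lte(d0, n * (n - 1))
  }
})

test_that("cross-validation folds the trace into contiguous blocks", {
  set.seed(13)
  n <- 40
  x <- matrix(runif(n * 2), n, 2, dimnames = list(NULL, c("k1", "k2")))
  y <- matrix(runif(n * 2), n, 2, dimnames = list(NULL, c("k1", "k2")))
  t <- (seq_len(2 * n) - 1) / 10
  seqp <- pose_sequence(t, rbind(x, x), rbind(y, y))
  lb <- label_timeline(c(0, n / 10), c(n / 10, 2 * n / 10), c("a", "b"))
  # folds = 1 equals compute_D on the first T_fold frames
  one <- compute_D_crossvalidated(seqp, c("k1", "k2"), c("a", "b"),
                                  folds = 1, T_fold = 10, labels = lb)
  direct <- compute_D(list(
    build_activity_vector(seqp, c("k1", "k2"), "a", 10, lb),
    build_activity_vector(seqp, c("k1", "k2"), "b", 10, lb)))
  expect_equal(one$score, direct$score)
  expect_identical(one$folds, 1L)
  # identical traces give 0 in every fold
  cv <- compute_D_crossvalidated(seqp, c("k1", "k2"), c("a", "b"),
                                 folds = 4, T_fold = 10, labels = lb)
  expect_equal(cv$score, 0)
  expect_equal(cv$fold_scores, rep(0, 4))
  expect_error(
    compute_D_crossvalidated(seqp, "k1", c("a", "b"), folds = 5, T_fold = 10,
                             labels = lb),
    "insufficient data")
})

test_that("fold-mean of a stationary signal stays close to single folds", {
  p <- tiny_protocol(activities = c("feeding", "make_bed"),
                     segment_duration_s = 40, seed = 17)
  rec <- simulate_recording(p, "s1", p$activities, with_imu = FALSE)
  seqp <- preprocess_pose(rec)
  cv <- compute_D_crossvalidated(seqp, DEFAULT_CANDIDATES,
                                 c("feeding", "make_bed"),
                                 folds = 4, T_fold = 100, labels = rec$labels)
  expect_lte(abs(cv$score - cv$fold_scores[1]), 2 * stats::sd(cv$fold_scores))
})

test_that("subset enumeration is complete and canonically ordered", {
  cs <- candidate_set()
  all5 <- enumerate_combinations(cs, 5)
  expect_length(all5, 31L)
  expect_identical(vapply(all5, length, integer(1)),
                   rep(1:5, choose(5, 1:5)))
  expect_identical(all5[[1]], "left_wrist")
  expect_identical(all5[[6]], c("left_wrist", "right_wrist"))
  expect_length(enumerate_combinations(letters[1:3], 3), 7L)
  expect_length(enumerate_combinations("a", 1), 1L)
  expect_error(enumerate_combinations(cs, 6), "max_size")
  expect_error(enumerate_combinations(cs, 0), "max_size")
})

test_that("ranking recovers a planted discriminative keypoint end to end", {
  p <- planted_keypoint_scenario(3, "left_ankle", seed = 23)
  rec <- simulate_recording(p, "s1", p$activities, with_imu = FALSE)
  ranking <- rank_placements(rec)
  expect_identical(nrow(ranking), 31L)
  expect_identical(best_subset_of_size(ranking, 1), "left_ankle")
  expect_identical(ranking$rank, 1:31)
  expect_true(!is.unsorted(rev(ranking$score)))
  expect_identical(sum(ranking$best_of_size), 5L)
})

test_that("ties are broken by size then canonical candidate order", {
  # two activities with bitwise-identical traces: every score is exactly 0
  n <- 60
  base <- constant_pose17(n, jitter = 0.02)
  xx <- rbind(base$x, base$x); yy <- rbind(base$y, base$y)
  seqp <- pose_sequence((seq_len(2 * n) - 1) / 10, xx, yy)
  rec <- recording("r1", "s1", list(), seqp,
                   label_timeline(c(0, n / 10), c(n / 10, 2 * n / 10),
                                  c("a", "b")))
  ranking <- rank_placements(rec, min_len = 50L, folds = 2L)
  expect_true(all(ranking$score < 1e-12))
  expect_identical(ranking$size, rep(1:5, choose(5, 1:5)))
  expect_identical(ranking$subset[[1]], "left_wrist")
  expect_identical(ranking$subset[[2]], "right_wrist")
})

test_that("activities shorter than the minimum length are refused by name", {
  p <- tiny_protocol(activities = c("feeding", "make_bed"),
                     segment_duration_s = 10, seed = 3)
  rec <- simulate_recording(p, "s1", p$activities, with_imu = FALSE)
  expect_error(rank_placements(rec),
               "'feeding' has 100 frames.*minimum sequence length of 500")
})
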