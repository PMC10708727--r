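# shared in-code fixtures

tiny_protocol <- function(activities = c("feeding", "make_bed"),
                          segment_duration_s = 10,
                          sensor_locations = c("right_wrist", "pelvis"),
                          seed = 42L, ...) {
  sim_protocol(n_subjects = 2L, activities = activities,
               segment_duration_s = segment_duration_s,
               sensor_locations = sensor_locations, seed = seed, ...)
}

tiny_recording <- function(subject_id = "s1", with_imu = TRUE, seed = 42L, ...) {
  p <- tiny_protocol(seed = seed, ...)
  simulate_recording(p, subject_id, p$activities, with_imu = with_imu)
}

# hand-built 17-keypoint pose frame sequence with constant coordinates
constant_pose17 <- function(n = 10, rate = 10, jitter = 0) {
  t <- (seq_len(n) - 1) / rate
  base <- harkit:::.BASE_POSE
  x <- matrix(rep(base[, "x"], each = n), n, 17,
              dimnames = list(NULL, KEYPOINTS_17))
  y <- matrix(rep(base[, "y"], each = n), n, 17,
              dimnames = list(NULL, KEYPOINTS_17))
  if (jitter > 0) {
    x <- x + matrix(stats::rnorm(n * 17, 0, jitter), n, 17)
    y <- y + matrix(stats::rnorm(n * 17, 0, jitter), n, 17)
  }
  pose_sequence(t, x, y)
}

# windowed dataset built directly from arrays, for split/model tests
fake_dataset <- function(n, window_len = 4L, n_features = 3L,
                         classes = c("a", "b"),
                         n_subjects = 2L, recs_per_subject = 2L, seed = 1L) {
  harkit:::with_seed(seed, {
    X <- array(stats::rnorm(n * window_len * n_features),
               c(n, window_len, n_features))
    labels <- sample(classes, n, replace = TRUE)
    subj <- sample(sprintf("subj%02d", seq_len(n_subjects)), n, replace = TRUE)
    rec <- paste0(subj, "_r", sample.int(recs_per_subject, n, replace = TRUE))
    harkit:::.windowed_dataset(X, labels, subj, rec,
                               paste0("f", seq_len(n_features)),
                               rep(FALSE, n_features))
  })
}

# linearly separable two-class windows: class mean differs in every feature
separable_dataset <- function(n_per_class = 12L, window_len = 8L,
                              n_features = 4L, seed = 1L) {
  harkit:::with_seed(seed, {
    n <- 2L * n_per_class
    X <- array(stats::rnorm(n * window_len * n_features, 0, 0.3),
               c(n, window_len, n_features))
    X[seq_len(n_per_class), , ] <- X[seq_len(n_per_class), , ] + 2
    labels <- rep(c("up", "down"), each = n_per_class)
    harkit:::.windowed_dataset(X, labels,
                               rep("subj01", n), rep("subj01_r1", n),
                               paste0("f", seq_len(n_features)),
                               rep(FALSE, n_features))
  })
}
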