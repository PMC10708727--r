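test_that("pose interpolation is linear, exact at frames, sentinel across gaps", {
  pose <- pose_sequence(c(0, 1), cbind(k = c(0.2, 0.4)), cbind(k = c(0.6, 0.8)))
  out <- interpolate_pose_at(pose, c(0, 0.5, 1), gap_max_s = 2)
  expect_equal(out[, "k_x"], c(0.2, 0.3, 0.4))
  expect_equal(out[, "k_y"], c(0.6, 0.7, 0.8))
  # bracketing gap above gap_max -> sentinel; outside the range -> sentinel
  out2 <- interpolate_pose_at(pose, c(-0.5, 0.5, 1.5), gap_max_s = 0.5)
  expect_equal(as.vector(out2[c(1, 2, 3), "k_x"]), c(-1, -1, -1))
  # exact frame hits survive even when the gap is unbridgeable
  out3 <- interpolate_pose_at(pose, c(0, 1), gap_max_s = 0.5)
  expect_equal(as.vector(out3[, "k_x"]), c(0.2, 0.4))
  # a missing bracketing value yields the sentinel for that query
  pose_na <- pose_sequence(c(0, 1, 2), cbind(k = c(0.2, NA, 0.4)),
                           cbind(k = c(0.6, NA, 0.8)))
  out4 <- interpolate_pose_at(pose_na, c(0.5, 1, 1.5), gap_max_s = 2)
  expect_equal(as.vector(out4[, "k_x"]), c(-1, -1, -1))
})

test_that("an empty pose stream yields all-sentinel rows, not an error", {
  expect_message(
    out <- interpolate_pose_at(NULL, c(0, 1), keypoints = c("a", "b")),
    "sentinel")
  expect_true(all(out == -1))
  expect_identical(dim(out), c(2L, 4L))
})

test_that("fused feature counts follow sensors x channels plus pose", {
  rec5 <- simulate_recording(
    tiny_protocol(sensor_locations = DEFAULT_CANDIDATES, segment_duration_s = 5),
    "s1", c("feeding", "make_bed"))
  imu_only <- fuse(rec5$imus, pose = NULL)
  expect_identical(ncol(imu_only$values), 70L)     # 5 x 14
  expect_false(any(imu_only$pose_cols))
  both <- fuse(rec5$imus, rec5$pose)
  expect_identical(ncol(both$values), 94L)         # 70 IMU + 12 x 2 pose
  expect_identical(sum(both$pose_cols), 24L)
  one <- fuse(rec5$imus["pelvis"], pose = NULL)
  expect_identical(ncol(one$values), 14L)
  expect_error(fuse(list(rec5$imus[[1]], rec5$imus[[1]])), "duplicate")
})

test_that("sentinels appear only in pose columns, only at gaps", {
  rec <- tiny_recording(segment_duration_s = 15)
  gappy <- inject_gaps(rec$pose, gap_rate = 4, gap_len_s = 2, seed = 3)
  series <- fuse(rec$imus, gappy)
  vals <- series$values
  expect_false(any(vals[, !series$pose_cols] == -1))
  pose_part <- vals[, series$pose_cols]
  expect_true(any(pose_part == -1))           # the gaps
  expect_true(any(pose_part != -1))           # the bridged spans
  # every all-sentinel row lies outside the pose range or in a wide gap
  gap_rows <- which(rowSums(pose_part == -1) == ncol(pose_part))
  for (r in gap_rows) {
    tt <- series$t[r]
    if (tt < min(gappy$t) || tt >= max(gappy$t)) next
    i <- max(which(gappy$t <= tt))
    expect_gt(gappy$t[i + 1] - gappy$t[i], 0.5)
  }
})

test_that("fused pose values reproduce source frames at coinciding times", {
  # pose frames sit exactly on the master grid (same arithmetic for both)
  n <- 50
  t <- (seq_len(n) - 1) / 10
  kp <- c("right_wrist", "pelvis")
  pose <- pose_sequence(t, matrix(runif(2 * n), n, 2, dimnames = list(NULL, kp)),
                        matrix(runif(2 * n), n, 2, dimnames = list(NULL, kp)))
  q <- interpolate_pose_at(pose, t, gap_max_s = 0.5)
  expect_identical(unname(q[, "right_wrist_x"]), unname(pose$x[, "right_wrist"]))
  expect_identical(unname(q[, "pelvis_y"]), unname(pose$y[, "pelvis"]))
})

test_that("window segmentation obeys the count formula and majority labels", {
  rec <- tiny_recording(segment_duration_s = 5)
  series <- fuse(rec$imus, rec$pose)
  lb <- rec$labels
  one <- make_windows(series, lb, window_len = 600, stride = 600)
  expect_identical(n_windows(one), 1L)
  two <- make_windows(series, lb, window_len = 300, stride = 300)
  expect_identical(n_windows(two), 2L)
  # floor((len - window)/stride) + 1 over assorted geometries
  len <- length(series$t)
  for (g in list(c(100, 50), c(250, 100), c(37, 12))) {
    ds <- make_windows(series, lb, window_len = g[1], stride = g[2])
    expect_identical(n_windows(ds),
                     as.integer((len - g[1]) %/% g[2] + 1L))
  }
  # a window covering 70% activity A and 30% B is labeled A
  lb2 <- label_timeline(c(0, 3.5), c(3.5, 5), c("feeding", "make_bed"))
  w <- make_windows(series, lb2, window_len = 300, stride = 300)
  expect_identical(w$labels[1], "feeding")   # 0-5 s window: 3.5 s vs 1.5 s
  # windows without label coverage are dropped
  lb3 <- label_timeline(0, 4.9, "feeding")
  w3 <- make_windows(series, lb3, window_len = 150, stride = 150)
  expect_identical(n_windows(w3), 2L)
  expect_warning(make_windows(series, lb, window_len = 10000), "shorter")
})

test_that("modality masking selects the promised column blocks", {
  rec <- tiny_recording(segment_duration_s = 5)
  ds <- windows_from_recording(rec, window_len = 60)
  expect_identical(dim(ds$X)[3], 2L * 14L + 24L)
  imu <- select_modality(ds, "imu")
  expect_identical(dim(imu$X)[3], 28L)
  pose <- select_modality(ds, "pose")
  expect_identical(dim(pose$X)[3], 24L)
  expect_true(all(startsWith(pose$feature_names, "pose.")))
  expect_identical(select_modality(ds, "both")$feature_names, ds$feature_names)
})
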