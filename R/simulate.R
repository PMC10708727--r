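#' @title Synthetic multimodal recording generator
#' @description Emulates the data model of a phone-camera pose estimator
#'   (17 keypoints at 10 Hz, normalized image coordinates with confidences)
#'   paired with body-worn IMUs (14 channels at 60 Hz) during scripted
#'   activity sessions, so the whole downstream pipeline is testable without
#'   hardware. Keypoint motion is an activity-specific sinusoid plus linear
#'   drift plus i.i.d. Gaussian noise; IMU channels are kinematically derived
#'   from the latent (noise-free) limb trajectory whose image projection gives
#'   the keypoints.
#' @name synthetic
NULL

# run expr with a local RNG seed, restoring global state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic 31-bit string hash (polynomial rolling hash)
.string_hash <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 131 + c) %% 2147483629
  as.integer(h)
}

# combine seed components in double precision, reduce below 2^31
.mix_seed <- function(...) {
  as.integer(sum(as.numeric(unlist(list(...)))) %% 2147483629)
}

.DEFAULT_ACTIVITIES <- c(
  "assist_dressing", "full_body_washing", "feeding", "make_bed", "clean_up",
  "skin_care", "push_wheelchair", "wheelchair_transfer", "comb_hair",
  "wipe_up", "prepare_medication", "serve_food", "documentation"
)

# canonical standing skeleton, normalized image coordinates (y grows downward)
.BASE_POSE <- local({
  m <- rbind(
    nose = c(0.50, 0.12), left_eye = c(0.48, 0.11), right_eye = c(0.52, 0.11),
    left_ear = c(0.46, 0.12), right_ear = c(0.54, 0.12),
    left_shoulder = c(0.42, 0.25), right_shoulder = c(0.58, 0.25),
    left_elbow = c(0.38, 0.38), right_elbow = c(0.62, 0.38),
    left_wrist = c(0.35, 0.50), right_wrist = c(0.65, 0.50),
    left_hip = c(0.45, 0.52), right_hip = c(0.55, 0.52),
    left_knee = c(0.44, 0.70), right_knee = c(0.56, 0.70),
    left_ankle = c(0.43, 0.88), right_ankle = c(0.57, 0.88)
  )
  colnames(m) <- c("x", "y")
  m[KEYPOINTS_17, , drop = FALSE]
})

.draw_motion_params <- function(activities, keypoints) {
  params <- list()
  for (a in activities) {
    pa <- list()
    for (kp in keypoints) {
      pa[[kp]] <- list(
        freq = stats::runif(2, 0.4, 2.5),      # Hz, per coordinate (x, y)
        amp = stats::runif(2, 0.02, 0.07),     # normalized image units
        phase = stats::runif(2, 0, 2 * pi),
        drift = stats::runif(2, -0.002, 0.002) # units per second
      )
    }
    params[[a]] <- pa
  }
  params
}

#' Define a simulation protocol
#'
#' A protocol fixes the study conditions: subjects, activity vocabulary,
#' per-activity per-keypoint motion parameters, sampling rates and noise
#' levels. The defaults emulate the structure of a nursing-activity study:
#' 10 subjects, 13 activities, 5 candidate sensor locations, pose at 10 Hz,
#' IMUs at 60 Hz.
#'
#' @param n_subjects Number of subjects the protocol is meant for.
#' @param activities Activity name vector (non-empty).
#' @param segment_duration_s Default duration of one scheduled activity
#'   segment, seconds.
#' @param pose_rate_hz,imu_rate_hz Sampling rates (defaults 10 and 60).
#' @param noise_sd Gaussian noise sd on keypoint coordinates (normalized
#'   units) and, reused, on IMU channels.
#' @param subject_sd Log-scale sd of per-subject frequency/amplitude factors
#'   plus baseline shifts; models inter-subject movement style.
#' @param sensor_locations Candidate locations simulated as IMU placements.
#' @param seed Integer seed; motion parameters are drawn deterministically
#'   from it when `params` is `NULL`.
#' @param params Optional explicit motion parameter list
#'   (`params[[activity]][[keypoint]]` with fields `freq`, `amp`, `phase`,
#'   `drift`, each length-2 for x and y).
#' @return Object of class `sim_protocol`.
#' @export
sim_protocol <- function(n_subjects = 10L,
                         activities = .DEFAULT_ACTIVITIES,
                         segment_duration_s = 60,
                         pose_rate_hz = 10, imu_rate_hz = 60,
                         noise_sd = 0.01, subject_sd = 0.15,
                         sensor_locations = DEFAULT_CANDIDATES,
                         seed = 1L, params = NULL) {
  if (length(activities) == 0L) stop("activities must be non-empty")
  if (pose_rate_hz <= 0 || imu_rate_hz <= 0) stop("rates must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (segment_duration_s <= 0) stop("segment_duration_s must be positive")
  if (is.null(params)) {
    params <- with_seed(seed, .draw_motion_params(activities, KEYPOINTS_17))
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 activities = as.character(activities),
                 segment_duration_s = segment_duration_s,
                 pose_rate_hz = pose_rate_hz, imu_rate_hz = imu_rate_hz,
                 noise_sd = noise_sd, subject_sd = subject_sd,
                 sensor_locations = as.character(sensor_locations),
                 seed = as.integer(seed), params = params),
            class = "sim_protocol")
}

#' @export
print.sim_protocol <- function(x, ...) {
  cat(sprintf(paste0("<sim_protocol> %d activities, %d subjects, ",
                     "pose %g Hz / IMU %g Hz, noise sd %g, seed %d\n"),
              length(x$activities), x$n_subjects, x$pose_rate_hz,
              x$imu_rate_hz, x$noise_sd, x$seed))
  invisible(x)
}

# per-subject style: multiplicative freq/amp factors and a baseline shift,
# deterministic in (protocol seed, subject id) and independent of the schedule
.subject_style <- function(protocol, subject_id) {
  with_seed(.mix_seed(protocol$seed * 7919, .string_hash(subject_id)), {
    list(freq_mult = exp(stats::rnorm(1, 0, protocol$subject_sd)),
         amp_mult = exp(stats::rnorm(1, 0, protocol$subject_sd)),
         shift = matrix(stats::rnorm(2 * 17, 0, protocol$subject_sd * 0.1),
                        17, 2, dimnames = list(KEYPOINTS_17, c("x", "y"))))
  })
}

# latent (noise-free) coordinate of keypoint kp at times t under a schedule;
# tau is time since segment start, so drift resets per segment
.latent_coord <- function(protocol, style, kp, coord, t, seg_act, seg_tau) {
  ci <- if (coord == "x") 1L else 2L
  base <- .BASE_POSE[kp, coord] + style$shift[kp, ci]
  out <- numeric(length(t))
  for (a in unique(seg_act)) {
    p <- protocol$params[[a]][[kp]]
    i <- seg_act == a
    out[i] <- base +
      style$amp_mult * p$amp[ci] *
        sin(2 * pi * style$freq_mult * p$freq[ci] * seg_tau[i] + p$phase[ci]) +
      p$drift[ci] * seg_tau[i]
  }
  out
}

# map times onto the schedule: active activity and segment-local time
.schedule_lookup <- function(schedule, t) {
  starts <- cumsum(c(0, schedule$duration_s))
  idx <- findInterval(t, starts, rightmost.closed = FALSE)
  idx[idx > nrow(schedule)] <- nrow(schedule)
  idx[idx < 1L] <- 1L
  list(activity = schedule$activity[idx], tau = t - starts[idx])
}

.normalize_schedule <- function(protocol, activity_schedule) {
  if (is.character(activity_schedule)) {
    activity_schedule <- data.frame(
      activity = activity_schedule,
      duration_s = protocol$segment_duration_s, stringsAsFactors = FALSE)
  }
  sch <- as.data.frame(activity_schedule)
  names(sch) <- c("activity", "duration_s")[seq_along(names(sch))]
  bad <- setdiff(sch$activity, protocol$activities)
  if (length(bad)) stop("unknown activity in schedule: ",
                        paste(unique(bad), collapse = ", "))
  if (any(sch$duration_s <= 0)) stop("schedule durations must be positive")
  sch
}

.quat_mult <- function(q, r) {
  c(q[1] * r[1] - q[2] * r[2] - q[3] * r[3] - q[4] * r[4],
    q[1] * r[2] + q[2] * r[1] + q[3] * r[4] - q[4] * r[3],
    q[1] * r[3] - q[2] * r[4] + q[3] * r[1] + q[4] * r[2],
    q[1] * r[4] + q[2] * r[3] - q[3] * r[2] + q[4] * r[1])
}

# simulate one IMU stream from the latent keypoint path of its location
.simulate_imu <- function(protocol, style, loc, duration, seg_fun, noise_sd) {
  rate <- protocol$imu_rate_hz
  n <- round(duration * rate)
  if (n < 2L) stop("schedule implies fewer than 2 IMU samples")
  t <- (seq_len(n) - 1L) / rate
  dt <- 1 / rate
  seg <- seg_fun(t)
  parts <- .candidate_raw_parts(loc)
  # latent position in meters: mean of constituent raw keypoints, scaled by
  # an assumed 1.7 m body height per normalized image unit; z is a small
  # out-of-plane oscillation reusing the x-parameters phase-shifted
  px <- py <- pz <- numeric(n)
  for (kp in parts) {
    px <- px + .latent_coord(protocol, style, kp, "x", t, seg$activity, seg$tau)
    py <- py + .latent_coord(protocol, style, kp, "y", t, seg$activity, seg$tau)
  }
  px <- 1.7 * px / length(parts); py <- 1.7 * py / length(parts)
  kp1 <- parts[1L]
  for (a in unique(seg$activity)) {
    p <- protocol$params[[a]][[kp1]]
    i <- seg$activity == a
    pz[i] <- 0.3 * p$amp[1] * sin(2 * pi * p$freq[1] * seg$tau[i] + p$phase[1] + pi / 3)
  }
  # acceleration: second-order central finite difference, edges replicated
  acc <- function(p) {
    a <- c(NA, diff(p, differences = 2), NA) / dt^2
    a[1] <- a[2]; a[n] <- a[n - 1L]
    a
  }
  A <- cbind(acc(px), acc(py), acc(pz)) +
    matrix(stats::rnorm(3L * n, 0, noise_sd), n, 3L)
  # angular rate: smooth activity-dependent 3-vector, small-angle integrated
  W3 <- matrix(0, n, 3L)
  for (a in unique(seg$activity)) {
    p <- protocol$params[[a]][[kp1]]
    i <- seg$activity == a
    W3[i, 1] <- 0.5 * sin(2 * pi * p$freq[1] * seg$tau[i] + p$phase[1])
    W3[i, 2] <- 0.5 * sin(2 * pi * p$freq[2] * seg$tau[i] + p$phase[2])
    W3[i, 3] <- 0.2 * cos(2 * pi * p$freq[1] * seg$tau[i])
  }
  Q <- matrix(0, n, 4L)
  q <- c(1, 0, 0, 0)
  Q[1L, ] <- q
  for (i in 2L:n) {
    w <- W3[i - 1L, ]
    th <- sqrt(sum(w^2)) * dt / 2
    ax <- if (th > 0) w / sqrt(sum(w^2)) else c(0, 0, 1)
    dq <- c(cos(th), sin(th) * ax)
    q <- .quat_mult(q, dq)
    q <- q / sqrt(sum(q^2))
    Q[i, ] <- q
  }
  # 4-channel angular velocity: per-sample quaternion difference over dt
  W4 <- rbind(Q[2L, ] - Q[1L, ], diff(Q)) / dt
  # magnetic field: slowly rotating unit vector plus noise
  M <- cbind(cos(0.01 * t), sin(0.01 * t), 0.5)
  M <- M / sqrt(rowSums(M^2)) +
    matrix(stats::rnorm(3L * n, 0, noise_sd), n, 3L)
  imu_sequence(loc, t, cbind(Q, W4, A, M))
}

#' Simulate one labeled multimodal recording
#'
#' Generates a pose stream (17 keypoints at `pose_rate_hz`), one IMU stream
#' per protocol sensor location at `imu_rate_hz`, and the label timeline
#' implied by the activity schedule. Identical `(protocol, subject_id,
#' activity_schedule)` yield bit-identical output.
#'
#' @param protocol A `sim_protocol`.
#' @param subject_id Subject identifier; determines the subject's movement
#'   style deterministically.
#' @param activity_schedule Either a character vector of activity names (each
#'   lasting `protocol$segment_duration_s`) or a data frame with columns
#'   `activity`, `duration_s`.
#' @param recording_id Identifier for the recording.
#' @param with_imu Set `FALSE` to generate a pose-only recording (faster for
#'   placement studies, which never touch the IMU streams).
#' @return A `recording`.
#' @export
simulate_recording <- function(protocol, subject_id, activity_schedule,
                               recording_id = paste0(subject_id, "_rec1"),
                               with_imu = TRUE) {
  sch <- .normalize_schedule(protocol, activity_schedule)
  duration <- sum(sch$duration_s)
  n_pose <- round(duration * protocol$pose_rate_hz)
  if (n_pose < 1L) stop("schedule implies fewer than 1 pose frame")
  style <- .subject_style(protocol, subject_id)
  seed_r <- .mix_seed(protocol$seed * 1000003, .string_hash(subject_id) * 31,
                      .string_hash(paste(sch$activity, collapse = "|")))
  with_seed(seed_r, {
    tp <- (seq_len(n_pose) - 1L) / protocol$pose_rate_hz
    seg <- .schedule_lookup(sch, tp)
    K <- length(KEYPOINTS_17)
    x <- y <- matrix(0, n_pose, K, dimnames = list(NULL, KEYPOINTS_17))
    for (k in seq_len(K)) {
      kp <- KEYPOINTS_17[k]
      x[, k] <- .latent_coord(protocol, style, kp, "x", tp, seg$activity, seg$tau)
      y[, k] <- .latent_coord(protocol, style, kp, "y", tp, seg$activity, seg$tau)
    }
    x <- x + matrix(stats::rnorm(n_pose * K, 0, protocol$noise_sd), n_pose, K)
    y <- y + matrix(stats::rnorm(n_pose * K, 0, protocol$noise_sd), n_pose, K)
    x <- pmin(pmax(x, 0), 1); y <- pmin(pmax(y, 0), 1)
    conf <- matrix(stats::runif(n_pose * K, 0.85, 1), n_pose, K)
    pose <- pose_sequence(tp, x, y, conf, KEYPOINTS_17)
    imus <- list()
    if (with_imu) {
      seg_fun <- function(t) .schedule_lookup(sch, t)
      for (loc in protocol$sensor_locations) {
        imus[[loc]] <- .simulate_imu(protocol, style, loc, duration, seg_fun,
                                     protocol$noise_sd)
      }
    }
    starts <- cumsum(c(0, sch$duration_s))
    labels <- label_timeline(starts[-length(starts)], starts[-1L], sch$activity)
    recording(recording_id, subject_id, imus, pose, labels,
              pose_rate_hz = protocol$pose_rate_hz,
              imu_rate_hz = protocol$imu_rate_hz)
  })
}

#' Remove pose frames inside randomly placed gaps
#'
#' Emulates occlusion: gap start times are drawn Poisson at `gap_rate` per
#' minute; frames with timestamps inside any `[start, start + gap_len_s)`
#' interval are dropped. Remaining frames are unchanged. Deterministic under
#' `seed`.
#'
#' @param seq A `pose_sequence`.
#' @param gap_rate Expected gaps per minute (>= 0).
#' @param gap_len_s Gap length in seconds (> 0).
#' @param seed Integer seed.
#' @return A `pose_sequence` with the gap frames removed.
#' @export
inject_gaps <- function(seq, gap_rate, gap_len_s, seed = 1L) {
  if (gap_rate < 0) stop("gap_rate must be non-negative")
  if (gap_len_s <= 0) stop("gap_len_s must be positive")
  if (gap_rate == 0) return(seq)
  span <- max(seq$t) - min(seq$t)
  with_seed(seed, {
    n_gaps <- stats::rpois(1, gap_rate * span / 60)
    if (n_gaps == 0L) return(seq)
    starts <- stats::runif(n_gaps, min(seq$t), max(seq$t))
    drop <- rep(FALSE, length(seq$t))
    for (s in starts) drop <- drop | (seq$t >= s & seq$t < s + gap_len_s)
    if (all(drop)) stop("gap injection removed every frame")
    pose_sequence(seq$t[!drop], seq$x[!drop, , drop = FALSE],
                  seq$y[!drop, , drop = FALSE],
                  seq$conf[!drop, , drop = FALSE], seq$keypoints)
  })
}

#' Protocol with one planted discriminative keypoint
#'
#' Builds a protocol in which every activity shares identical motion
#' parameters at every keypoint except the designated candidate location,
#' where frequency and amplitude differ per activity. Ground truth for
#' placement-recovery experiments: the planted location is the only one whose
#' traces distinguish the activities beyond noise.
#'
#' @param n_activities Number of activities (>= 2).
#' @param discriminative_keypoint One of the default candidate locations, or
#'   `NULL` for the fully degenerate control (identical parameters
#'   everywhere).
#' @param seed Integer seed for the shared parameter draw.
#' @param noise_sd Keypoint noise sd (default 0.01).
#' @param segment_duration_s Segment length, seconds (default 60, i.e. 600
#'   pose frames per activity at 10 Hz).
#' @return A `sim_protocol`.
#' @export
planted_keypoint_scenario <- function(n_activities, discriminative_keypoint,
                                      seed = 1L, noise_sd = 0.01,
                                      segment_duration_s = 60) {
  if (n_activities < 2L) stop("need at least 2 activities")
  if (!is.null(discriminative_keypoint) &&
      !discriminative_keypoint %in% DEFAULT_CANDIDATES) {
    stop("discriminative keypoint must be one of: ",
         paste(DEFAULT_CANDIDATES, collapse = ", "))
  }
  activities <- sprintf("activity_%02d", seq_len(n_activities))
  shared <- with_seed(seed, .draw_motion_params("shared", KEYPOINTS_17)$shared)
  params <- stats::setNames(
    replicate(n_activities, shared, simplify = FALSE), activities)
  if (!is.null(discriminative_keypoint)) {
    raw <- .candidate_raw_parts(discriminative_keypoint)
    for (i in seq_len(n_activities)) {
      for (kp in raw) {
        p <- shared[[kp]]
        p$freq <- rep(0.4 + 0.5 * i, 2)
        p$amp <- rep(0.02 + 0.012 * i, 2)
        params[[i]][[kp]] <- p
      }
    }
  }
  sim_protocol(n_subjects = 1L, activities = activities,
               segment_duration_s = segment_duration_s,
               noise_sd = noise_sd, subject_sd = 0,
               seed = seed, params = params)
}
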