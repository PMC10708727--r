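#' @title Built-in validation experiments
#' @description Two self-contained synthetic studies used to validate the
#'   toolkit end to end: recovery of a planted discriminative sensor location
#'   by the placement metric, and last-layer personalization of a pretrained
#'   classifier on a held-out subject.
#' @name experiments
NULL

#' Placement-recovery experiment
#'
#' For each seed, generates a planted-keypoint recording (all activities
#' identical except at the designated location), runs the full placement
#' pipeline and checks whether that location is the top-ranked single-sensor
#' placement.
#'
#' @param n_seeds Number of independent replicates (default 20).
#' @param n_activities Activities per replicate (default 3).
#' @param keypoint Planted location (default "right_wrist").
#' @param noise_sd Keypoint noise sd (default 0.01).
#' @param segment_duration_s Seconds per activity (default 60, i.e. 600
#'   frames at 10 Hz).
#' @param base_seed Offset added to the replicate index.
#' @return List with `hits` (logical per seed) and `rate` (fraction
#'   recovered).
#' @export
placement_recovery <- function(n_seeds = 20L, n_activities = 3L,
                               keypoint = "right_wrist", noise_sd = 0.01,
                               segment_duration_s = 60, base_seed = 0L) {
  hits <- vapply(seq_len(n_seeds), function(s) {
    p <- planted_keypoint_scenario(n_activities, keypoint,
                                   seed = base_seed + s,
                                   noise_sd = noise_sd,
                                   segment_duration_s = segment_duration_s)
    rec <- simulate_recording(p, sprintf("subj%02d", s), p$activities,
                              with_imu = FALSE)
    ranking <- rank_placements(rec)
    identical(best_subset_of_size(ranking, 1L), keypoint)
  }, logical(1))
  list(hits = hits, rate = mean(hits))
}

#' Subject-personalization (transfer-learning) experiment
#'
#' One replicate of the on-device personalization protocol: simulate a small
#' cohort with marked inter-subject movement variability, pretrain a
#' classifier on all subjects but one (the leave-one-subject-out reference),
#' then fine-tune only the final layer on 80% of the held-out subject's
#' recordings and compare held-out accuracy before and after.
#'
#' @param seed Replicate seed; drives the cohort simulation and training.
#' @param arch Architecture name (default "cnn_lstm").
#' @param n_subjects Cohort size (default 4; the held-out subject is the
#'   last).
#' @param n_activities Activities (default 3).
#' @param n_recordings Recordings per subject (default 5, so the held-out
#'   subject supports a true 80:20 recordings split).
#' @param segment_duration_s Seconds per activity per recording (default 8).
#' @param window_len Window length in samples (default 60, i.e. 1 s at
#'   60 Hz; desk-scale stand-in for the 10-s production window).
#' @param subject_sd Inter-subject variability (default 0.4; pronounced
#'   personal styles, the regime where personalization pays off).
#' @param pretrain_epochs,pretrain_lr Pretraining schedule.
#' @param epochs,batch_size Fine-tuning schedule (defaults 10 and 7).
#' @return List with `before`/`after` accuracy, the two `eval_report`s and
#'   the fine-tuned model.
#' @export
personalization_experiment <- function(seed = 1L, arch = "cnn_lstm",
                                       n_subjects = 4L, n_activities = 3L,
                                       n_recordings = 5L,
                                       segment_duration_s = 8,
                                       window_len = 60L, subject_sd = 0.4,
                                       pretrain_epochs = 6L,
                                       pretrain_lr = 1e-3,
                                       epochs = 10L, batch_size = 7L) {
  acts <- sprintf("activity_%02d", seq_len(n_activities))
  p <- sim_protocol(n_subjects = n_subjects, activities = acts,
                    segment_duration_s = segment_duration_s,
                    sensor_locations = "right_wrist",
                    subject_sd = subject_sd, seed = seed)
  subjects <- sprintf("subj%02d", seq_len(n_subjects))
  recs <- list()
  for (s in subjects) {
    for (r in seq_len(n_recordings)) {  # shuffled activity order per recording
      sched <- with_seed(.string_hash(paste(s, r, seed)), sample(acts))
      recs[[paste(s, r)]] <- simulate_recording(
        p, s, sched, recording_id = sprintf("%s_rec%d", s, r))
    }
  }
  ds <- build_dataset(recs, window_len = window_len, stride = window_len,
                      modality = "imu")
  held <- subjects[n_subjects]
  pre_idx <- which(ds$subject_id != held)
  new_idx <- which(ds$subject_id == held)
  spec <- model_spec(arch, window_len, dim(ds$X)[3L], acts,
                     filters = 8L, units = 8L, seed = seed)
  model <- build_architecture(spec)
  model <- train(model, subset_windows(ds, pre_idx),
                 epochs = pretrain_epochs, lr = pretrain_lr, seed = seed)
  ft <- fine_tune(model, subset_windows(ds, new_idx), epochs = epochs,
                  batch_size = batch_size, seed = seed)
  list(before = ft$before$accuracy, after = ft$after$accuracy,
       report_before = ft$before, report_after = ft$after,
       model = ft$model)
}
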