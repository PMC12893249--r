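## ---- canned experiments: end-to-end detection and parameter recovery -------

#' End-to-end synthetic detection experiment
#'
#' Generates a synthetic cohort at the reference prevalence, trains the
#' detector on most recordings, and scores window-level detection on the
#' held-out recordings at the deployed 0.99 threshold. This is the package's
#' standing check that the whole pipeline (synthesis -> MTF -> CNN ->
#' decision) learns the detection task.
#'
#' @param n_recordings Cohort size (default 20).
#' @param minutes Minutes per recording (default 10).
#' @param n_val Recordings held out for epoch selection and probability
#'   calibration (default 3).
#' @param n_test Recordings held out from *all* of training, selection, and
#'   calibration, on which the metrics are computed (default 4).
#' @param seed Master seed (default 7).
#' @param threshold Decision threshold (default 0.99).
#' @param config A [training_config()] (seed is overridden by `seed`).
#' @param prevalence Bursts per minute (default 2.2).
#' @return List: `model`, `metrics` (pooled window-level
#'   `detection_outcome` over the test recordings), `event_sensitivity`,
#'   `fp_rate_per_min`, `per_recording` data frame.
#' @export
run_detection_experiment <- function(n_recordings = 20L, minutes = 10,
                                     n_val = 3L, n_test = 4L, seed = 7L,
                                     threshold = 0.99,
                                     config = training_config(),
                                     prevalence = 2.2) {
  config$seed <- as.integer(seed)
  rc <- recording_config(duration_s = minutes * 60,
                         target_prevalence_per_min = prevalence, seed = seed)
  cohort <- generate_cohort(rc, n_recordings, seed = seed)
  n_tr <- n_recordings - n_val - n_test
  model <- train_detector(cohort[seq_len(n_tr)],
                          cohort[n_tr + seq_len(n_val)], config)
  n_tr <- n_tr + n_val                  # test recordings follow the val block
  rule <- decision_rule(threshold)
  timing <- loop_timing()
  policy <- trigger_policy()
  pred <- truth <- integer(0)
  probs <- numeric(0)
  per_rec <- list()
  ev_tp <- ev_n <- fp_trig <- 0
  for (vi in seq_len(n_test)) {
    rec <- cohort[[n_tr + vi]]
    cr <- classify_recording(model, rec, rule)
    pred <- c(pred, cr$predicted)
    truth <- c(truth, cr$truth)
    probs <- c(probs, cr$probabilities)
    trig <- run_stream(rec, model, timing, policy, rule, model$wparams)
    b <- rec$bursts
    dm <- detection_metrics(cr$predicted, cr$truth,
                            burst_intervals = cbind(b$onset_s,
                                                    b$onset_s + b$duration_s),
                            trigger_times_s = trig$trigger_time_s)
    ev_tp <- ev_tp + (dm$event_tp %||% 0)
    ev_n <- ev_n + nrow(b)
    fp_trig <- fp_trig + sum(trig$eeg_state_truth == "normal")
    per_rec[[vi]] <- data.frame(
      recording = n_tr + vi, n_bursts = nrow(b),
      sensitivity = dm$sensitivity, specificity = dm$specificity,
      event_sensitivity = dm$event_sensitivity,
      n_triggers = nrow(trig))
  }
  metrics <- detection_metrics(pred, truth, probabilities = probs)
  list(model = model, metrics = metrics,
       event_sensitivity = if (ev_n > 0) ev_tp / ev_n else NA_real_,
       fp_rate_per_min = fp_trig / (n_test * minutes),
       per_recording = do.call(rbind, per_rec))
}

#' Reaction-time prolongation recovery experiment
#'
#' Simulates car-test sessions with a known injected RT prolongation and
#' recovers it with [delta_rt()]; reports bias and RMSE over seeds. Triggers
#' are laid out directly (half during bursts, half during normal EEG) so the
#' experiment isolates the estimator from the detector.
#'
#' @param deltas Injected prolongations in ms (default 20, 60, 100).
#' @param n_trials Trials per EEG state (default 100).
#' @param n_seeds Replicates (default 20).
#' @param seed Master seed.
#' @param subject Baseline [subject_model()] (its `delta_rt_ms` is swept).
#' @return Data frame per delta: `delta`, `bias_ms`, `rmse_ms`, `mean_est`.
#' @export
delta_rt_recovery <- function(deltas = c(20, 60, 100), n_trials = 100L,
                              n_seeds = 20L, seed = 1L,
                              subject = subject_model()) {
  trig <- data.frame(
    trigger_time_s = seq_len(2 * n_trials) * 2,
    window_start = 0L, probability = 1,
    eeg_state_truth = rep(c("ied", "normal"), each = n_trials))
  out <- lapply(deltas, function(d) {
    subj <- subject
    subj$delta_rt_ms <- d
    est <- vapply(seq_len(n_seeds), function(s) {
      log <- simulate_car_test(trig, subj, seed = derive_seed(seed, "rec", d, s))
      ied <- log$eeg_state_truth == "ied"
      delta_rt(log$response_time_ms[ied], log$response_time_ms[!ied])
    }, 0)
    data.frame(delta = d, bias_ms = mean(est) - d,
               rmse_ms = sqrt(mean((est - d)^2)), mean_est = mean(est))
  })
  do.call(rbind, out)
}
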