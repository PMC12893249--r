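## ---- closed-loop trigger simulation and virtual subjects -------------------

#' Loop timing model
#'
#' Timing of the simulated real-time path: EEG arrives in packets, each
#' window is transformed and classified within a processing budget, and the
#' trigger-to-stimulus path adds a digital latency drawn from a configurable
#' distribution (log-normal scaled to a 68 ms median by default, sigma such
#' that observed per-trigger latencies in the low-40s to mid-70s ms fall
#' within the central 80%).
#'
#' @param packet_ms Streaming granularity in ms (default 100).
#' @param processing_ms Per-window transform+classify budget in ms
#'   (default 100).
#' @param digital_latency_model List describing the trigger-to-stimulus
#'   delay: `type` one of `"lognormal"` or `"constant"`, `median_ms`,
#'   `sdlog`.
#' @return An object of class `loop_timing`.
#' @export
loop_timing <- function(packet_ms = 100, processing_ms = 100,
                        digital_latency_model = list(type = "lognormal",
                                                     median_ms = 68,
                                                     sdlog = 0.35)) {
  if (packet_ms < 0 || processing_ms < 0) {
    sl_stop("delays must be >= 0", "spikeloop_invalid_configuration")
  }
  structure(list(packet_ms = packet_ms, processing_ms = processing_ms,
                 digital_latency_model = digital_latency_model),
            class = "loop_timing")
}

#' Trigger policy
#'
#' @param refractory_s Minimum spacing between consecutive triggers in
#'   seconds (default 1.0, tied to the 1 s response deadline); a long burst
#'   can therefore fire several triggers.
#' @return An object of class `trigger_policy`.
#' @export
trigger_policy <- function(refractory_s = 1.0) {
  if (refractory_s < 0) {
    sl_stop("refractory_s must be >= 0", "spikeloop_invalid_configuration")
  }
  structure(list(refractory_s = refractory_s), class = "trigger_policy")
}

#' Virtual subject model
#'
#' Response behavior of the simulated patient: a Gaussian baseline
#' reaction-time distribution, an additive RT shift during IED-bursts, a
#' response deadline (missing it is a virtual crash in the car test), and
#' per-state probabilities of incorrect/missed answers to the brief
#' cognitive probes.
#'
#' @param rt_normal_mean_ms,rt_normal_sd_ms Baseline RT distribution (ms).
#' @param delta_rt_ms Additive RT shift during IED-bursts (ms).
#' @param miss_deadline_ms Response window (default 1000 ms).
#' @param iart_error_prob_normal,iart_error_prob_ied Probability of an
#'   incorrect response during normal EEG / IED-bursts.
#' @param iart_miss_prob_normal,iart_miss_prob_ied Probability of a missed
#'   response during normal EEG / IED-bursts.
#' @param seed Integer seed.
#' @return An object of class `subject_model`.
#' @export
subject_model <- function(rt_normal_mean_ms = 550, rt_normal_sd_ms = 100,
                          delta_rt_ms = 50, miss_deadline_ms = 1000,
                          iart_error_prob_normal = 0.005,
                          iart_error_prob_ied = 0.025,
                          iart_miss_prob_normal = 0,
                          iart_miss_prob_ied = 0.03, seed = 1L) {
  probs <- c(iart_error_prob_normal, iart_error_prob_ied,
             iart_miss_prob_normal, iart_miss_prob_ied)
  if (any(probs < 0 | probs > 1)) {
    sl_stop("probabilities must lie in [0, 1]", "spikeloop_invalid_configuration")
  }
  if (miss_deadline_ms <= 0) {
    sl_stop("deadline must be > 0", "spikeloop_invalid_configuration")
  }
  structure(list(rt_normal_mean_ms = rt_normal_mean_ms,
                 rt_normal_sd_ms = rt_normal_sd_ms, delta_rt_ms = delta_rt_ms,
                 miss_deadline_ms = miss_deadline_ms,
                 iart_error_prob_normal = iart_error_prob_normal,
                 iart_error_prob_ied = iart_error_prob_ied,
                 iart_miss_prob_normal = iart_miss_prob_normal,
                 iart_miss_prob_ied = iart_miss_prob_ied,
                 seed = as.integer(seed)),
            class = "subject_model")
}

#' Sample digital latencies
#'
#' @param model A `digital_latency_model` list (see [loop_timing()]).
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return Nonnegative latencies in ms; with the default log-normal model the
#'   sample median over many draws sits at 68 ms.
#' @export
sample_digital_latency <- function(model, n = 1L, seed = 1L) {
  with_seed(derive_seed(seed, "latency"), {
    switch(model$type,
           lognormal = stats::rlnorm(n, meanlog = log(model$median_ms),
                                     sdlog = model$sdlog),
           constant = rep(model$median_ms, n),
           sl_stop("unknown digital latency model", "spikeloop_invalid_configuration"))
  })
}

#' Stream a recording through the detector and emit triggers
#'
#' Event-driven simulation of the real-time loop: windows are evaluated in
#' arrival order with availability time = window end time + packet delay +
#' processing delay; a positively classified window emits a trigger unless
#' one fired within the preceding refractory interval. Each trigger is tagged
#' with the truth label of the window that fired it (the >=150-sample
#' majority rule), which is how triggers are scored true- or false-positive.
#'
#' @param recording A `labeled_recording` (at least one window long).
#' @param model An `ied_detector`, or `"oracle"` for a truth-fed classifier.
#' @param timing A [loop_timing()].
#' @param policy A [trigger_policy()].
#' @param rule A [decision_rule()].
#' @param wparams Windowing parameters used when `model = "oracle"`.
#' @return A data frame of triggers: `trigger_time_s`, `window_start`,
#'   `probability`, `eeg_state_truth` (`"ied"`/`"normal"`).
#' @export
run_stream <- function(recording, model, timing = loop_timing(),
                       policy = trigger_policy(), rule = decision_rule(),
                       wparams = windowing_params()) {
  if (identical(model, "oracle")) {
    ws <- frame_windows(recording, wparams)
    probs <- as.numeric(ws$label)
    pred <- ws$label
  } else {
    cr <- classify_recording(model, recording, rule)
    ws <- cr$windows
    probs <- cr$probabilities
    pred <- cr$predicted
  }
  fs <- ws$params$fs_hz
  avail_s <- (ws$starts + ws$params$window_len) / fs +
    (timing$packet_ms + timing$processing_ms) / 1000
  out <- list()
  last_trig <- -Inf
  for (i in seq_along(avail_s)) {
    if (pred[i] == 1 && avail_s[i] - last_trig >= policy$refractory_s) {
      last_trig <- avail_s[i]
      out[[length(out) + 1]] <- data.frame(
        trigger_time_s = avail_s[i], window_start = ws$starts[i],
        probability = probs[i],
        eeg_state_truth = if (ws$label[i] == 1) "ied" else "normal")
    }
  }
  if (length(out) == 0) {
    return(data.frame(trigger_time_s = numeric(0), window_start = integer(0),
                      probability = numeric(0), eeg_state_truth = character(0)))
  }
  do.call(rbind, out)
}

#' Simulate the car test for a trigger list
#'
#' Each trigger presents an obstacle after the sampled digital latency. The
#' reaction time is drawn from the subject's baseline distribution, shifted
#' by `delta_rt_ms` when the trigger fell inside a true IED-burst; RT
#' measurement starts at stimulus onset (the on-screen appearance, emulating
#' the photo-sensor correction of the hardware loop). A response slower than
#' the deadline is a virtual crash and its RT is recorded as missing.
#'
#' @param triggers Time-ordered trigger data frame from [run_stream()].
#' @param subject A [subject_model()].
#' @param timing A [loop_timing()].
#' @param seed Integer seed (defaults to the subject's).
#' @return An `event_log` data frame: trigger/stimulus times, latency, EEG
#'   state, `response_time_ms`, `missed`, `crash`.
#' @export
simulate_car_test <- function(triggers, subject, timing = loop_timing(),
                              seed = subject$seed) {
  n <- nrow(triggers)
  lat <- sample_digital_latency(timing$digital_latency_model, n,
                                seed = derive_seed(seed, "car-lat"))
  rt <- with_seed(derive_seed(seed, "car-rt"), {
    base <- stats::rnorm(n, subject$rt_normal_mean_ms, subject$rt_normal_sd_ms)
    pmax(base + ifelse(triggers$eeg_state_truth == "ied",
                       subject$delta_rt_ms, 0), 1)
  })
  crash <- rt > subject$miss_deadline_ms
  log <- data.frame(
    trigger_time_s = triggers$trigger_time_s,
    digital_latency_ms = lat,
    stimulus_onset_s = triggers$trigger_time_s + lat / 1000,
    eeg_state_truth = triggers$eeg_state_truth,
    response_time_ms = ifelse(crash, NA_real_, rt),
    missed = crash,
    crash = crash)
  attr(log, "test_type") <- "car"
  class(log) <- c("event_log", class(log))
  log
}

#' Simulate the cognitive probe test (iART) for a trigger list
#'
#' Each trigger plays a brief neuropsychological task video; the response is
#' drawn as correct / incorrect / missed with the subject's per-state
#' probabilities. A hook scales the miss probability with burst duration
#' when `duration_miss_scale > 0` and burst durations are supplied.
#'
#' @param triggers Time-ordered trigger data frame from [run_stream()].
#' @param subject A [subject_model()].
#' @param timing A [loop_timing()].
#' @param burst_duration_s Optional per-trigger burst durations for the
#'   duration hook.
#' @param duration_miss_scale Additional miss probability per second of burst
#'   duration (default 0 = off).
#' @param seed Integer seed.
#' @return An `event_log` data frame with `response_class` in
#'   `{"correct", "incorrect", "missed"}`.
#' @export
simulate_iart <- function(triggers, subject, timing = loop_timing(),
                          burst_duration_s = NULL, duration_miss_scale = 0,
                          seed = subject$seed) {
  n <- nrow(triggers)
  lat <- sample_digital_latency(timing$digital_latency_model, n,
                                seed = derive_seed(seed, "iart-lat"))
  ied <- triggers$eeg_state_truth == "ied"
  p_err <- ifelse(ied, subject$iart_error_prob_ied,
                  subject$iart_error_prob_normal)
  p_miss <- ifelse(ied, subject$iart_miss_prob_ied,
                   subject$iart_miss_prob_normal)
  if (!is.null(burst_duration_s) && duration_miss_scale > 0) {
    p_miss <- pmin(1, p_miss + ifelse(ied, duration_miss_scale *
                                        burst_duration_s, 0))
  }
  if (any(p_err + p_miss > 1)) {
    sl_stop("error + miss probability exceeds 1",
            "spikeloop_invalid_configuration")
  }
  cls <- with_seed(derive_seed(seed, "iart"), {
    u <- stats::runif(n)
    ifelse(u < p_miss, "missed",
           ifelse(u < p_miss + p_err, "incorrect", "correct"))
  })
  log <- data.frame(
    trigger_time_s = triggers$trigger_time_s,
    digital_latency_ms = lat,
    stimulus_onset_s = triggers$trigger_time_s + lat / 1000,
    eeg_state_truth = triggers$eeg_state_truth,
    response_class = cls)
  attr(log, "test_type") <- "iart"
  class(log) <- c("event_log", class(log))
  log
}

#' Write an event log as CSV or JSON lines
#'
#' @param log An `event_log`.
#' @param path Output path; format chosen by extension (`.csv` or `.jsonl`).
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path) {
  if (grepl("\\.jsonl$", path)) {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(log))) {
      writeLines(jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE,
                                  na = "null", digits = NA), con)
    }
  } else {
    utils::write.csv(log, path, row.names = FALSE)
  }
  invisible(path)
}
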