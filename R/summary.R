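## ---- session rows and cohort aggregates ------------------------------------

table1_columns <- c("patient", "duration_min", "n_triggers", "n_ieds",
                    "mean_rt_normal_ms", "delta_rt_ms",
                    "ied_dur_no_crash_ms", "n_crashes_ied",
                    "ied_dur_crash_ms", "n_crashes_normal",
                    "p_crash_ied_pct", "p_crash_normal_pct",
                    "p_crash_due_ied_pct", "cum_crash_risk_pct",
                    "sensitivity", "specificity", "fp_rate_per_min")

table2_columns <- c("patient", "duration_min", "n_triggers", "n_ieds",
                    "n_incorrect_normal", "n_missed_normal", "n_correct_ied",
                    "n_incorrect_ied", "n_missed_ied",
                    "p_incorrect_normal_pct", "p_missed_normal_pct",
                    "p_incorrect_ied_pct", "p_missed_ied_pct",
                    "p_incorrect_due_ied_pct", "p_missed_due_ied_pct",
                    "sensitivity", "specificity", "fp_rate_per_min")

## burst duration (ms) containing each trigger's firing window, NA when the
## trigger fell in normal EEG
trigger_burst_duration_ms <- function(log, recording, wparams) {
  if (nrow(recording$bursts) == 0 || nrow(log) == 0) {
    return(rep(NA_real_, nrow(log)))
  }
  b <- recording$bursts
  centre_s <- (log$trigger_time_s)  # trigger time trails the window slightly
  vapply(seq_len(nrow(log)), function(i) {
    hit <- which(centre_s[i] >= b$onset_s &
                   centre_s[i] <= b$onset_s + b$duration_s + 1)
    if (length(hit) == 0) NA_real_ else b$duration_s[hit[1]] * 1000
  }, 0)
}

#' Summarize one test session
#'
#' Fills a one-row session summary in the car-test or cognitive-probe schema
#' from an event log, the underlying recording, and the window-level
#' detection outcome. Undefined cells (e.g. burst-effect columns in a
#' session without IED-bursts) are missing, not zero. Crash/response
#' denominators follow the session-level definitions: IED-state percentages
#' are relative to the number of true-positive triggers, normal-state
#' percentages relative to the number of false-positive triggers.
#'
#' @param event_log An `event_log` from [simulate_car_test()] or
#'   [simulate_iart()].
#' @param recording The `labeled_recording` the session ran on.
#' @param detection A `detection_outcome` for the session (window level).
#' @param patient_id Identifier for the summary row.
#' @return One-row data frame in the matching table schema.
#' @export
session_summary <- function(event_log, recording, detection,
                            patient_id = 1L) {
  test_type <- attr(event_log, "test_type") %||% "car"
  duration_min <- length(recording$samples) / recording$fs_hz / 60
  ied <- event_log$eeg_state_truth == "ied"
  n_triggers <- nrow(event_log)
  n_ieds <- sum(ied)
  n_fp <- sum(!ied)
  out <- data.frame(patient = patient_id, duration_min = duration_min,
                    n_triggers = n_triggers, n_ieds = n_ieds)
  if (test_type == "car") {
    rts_ied <- event_log$response_time_ms[ied]
    rts_norm <- event_log$response_time_ms[!ied]
    dur_ms <- trigger_burst_duration_ms(event_log, recording,
                                        windowing_params())
    crash_ied <- sum(event_log$crash & ied)
    crash_norm <- sum(event_log$crash & !ied)
    cp <- crash_probabilities(crash_ied, n_ieds, crash_norm, n_fp)
    drt <- delta_rt(rts_ied, rts_norm)
    out$mean_rt_normal_ms <- if (all(is.na(rts_norm))) NA_real_ else
      mean(rts_norm, na.rm = TRUE)
    out$delta_rt_ms <- drt
    out$ied_dur_no_crash_ms <- if (any(ied & !event_log$crash)) {
      mean(dur_ms[ied & !event_log$crash], na.rm = TRUE)
    } else NA_real_
    out$n_crashes_ied <- if (n_ieds > 0) crash_ied else NA_integer_
    out$ied_dur_crash_ms <- if (any(ied & event_log$crash)) {
      mean(dur_ms[ied & event_log$crash], na.rm = TRUE)
    } else NA_real_
    out$n_crashes_normal <- if (n_fp > 0) crash_norm else NA_integer_
    out$p_crash_ied_pct <- cp$p_ied_pct
    out$p_crash_normal_pct <- cp$p_normal_pct
    out$p_crash_due_ied_pct <- cp$p_due_ied_pct
    out$cum_crash_risk_pct <- if (is.na(drt)) NA_real_ else
      cumulative_crash_risk(drt)
  } else {
    cls <- event_log$response_class
    ip <- iart_probabilities(
      n_incorrect_ied = sum(ied & cls == "incorrect"),
      n_missed_ied = sum(ied & cls == "missed"), n_ied = n_ieds,
      n_incorrect_normal = sum(!ied & cls == "incorrect"),
      n_missed_normal = sum(!ied & cls == "missed"), n_fp_triggers = n_fp)
    out$n_incorrect_normal <- sum(!ied & cls == "incorrect")
    out$n_missed_normal <- sum(!ied & cls == "missed")
    out$n_correct_ied <- sum(ied & cls == "correct")
    out$n_incorrect_ied <- sum(ied & cls == "incorrect")
    out$n_missed_ied <- sum(ied & cls == "missed")
    out$p_incorrect_normal_pct <- ip$p_incorrect_normal_pct
    out$p_missed_normal_pct <- ip$p_missed_normal_pct
    out$p_incorrect_ied_pct <- ip$p_incorrect_ied_pct
    out$p_missed_ied_pct <- ip$p_missed_ied_pct
    out$p_incorrect_due_ied_pct <- ip$p_incorrect_due_ied_pct
    out$p_missed_due_ied_pct <- ip$p_missed_due_ied_pct
  }
  out$sensitivity <- detection$sensitivity
  out$specificity <- detection$specificity
  out$fp_rate_per_min <- fp_rate_per_min(n_fp, duration_min)
  out
}

#' Cohort summary of session rows
#'
#' Per column: sample mean, sample SD (n-1 denominator; missing for a single
#' value), count of non-missing entries, median (midpoint of the central
#' pair for even n), and a distribution-free 95% CI for the median from
#' order statistics ([median_ci()]). Columns use pairwise deletion, so the
#' count row mirrors per-column availability. Values are kept at full
#' precision; rounding happens only at presentation.
#'
#' @param rows Data frame of session rows (one per patient/session).
#' @param columns Columns to summarize (default: all numeric except
#'   `patient`).
#' @return Data frame of class `cohort_summary`: one row per column with
#'   `mean`, `sd`, `count`, `median`, `ci_low`, `ci_high`.
#' @export
cohort_summary <- function(rows, columns = NULL) {
  columns <- columns %||% setdiff(names(rows)[vapply(rows, is.numeric, TRUE)],
                                  "patient")
  out <- do.call(rbind, lapply(columns, function(cn) {
    x <- rows[[cn]]
    x <- x[!is.na(x)]
    if (length(x) == 0) {
      return(data.frame(column = cn, mean = NA_real_, sd = NA_real_,
                        count = 0L, median = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_))
    }
    ci <- median_ci(x)
    data.frame(column = cn, mean = mean(x),
               sd = if (length(x) > 1) stats::sd(x) else NA_real_,
               count = length(x), median = unname(ci["median"]),
               ci_low = unname(ci["ci_low"]), ci_high = unname(ci["ci_high"]))
  }))
  class(out) <- c("cohort_summary", class(out))
  out
}
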