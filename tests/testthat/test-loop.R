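test_that("digital latency model is calibrated to a 68 ms median", {
  lat <- sample_digital_latency(loop_timing()$digital_latency_model, 10000,
                                seed = 1)
  expect_true(all(lat >= 0))
  expect_gte(median(lat), 65)
  expect_lte(median(lat), 71)
  ## constant model and determinism
  expect_equal(sample_digital_latency(list(type = "constant", median_ms = 0),
                                      5, seed = 1), rep(0, 5))
  expect_identical(sample_digital_latency(loop_timing()$digital_latency_model,
                                          100, seed = 3),
                   sample_digital_latency(loop_timing()$digital_latency_model,
                                          100, seed = 3))
})

test_that("oracle streaming triggers only and always inside bursts", {
  ## no bursts -> no triggers
  bg <- generate_background(fix_config(seed = 41))
  trig0 <- run_stream(bg, "oracle")
  expect_equal(nrow(trig0), 0)
  ## one 2.5 s burst, refractory 1 s -> 2-3 triggers, all true-positive
  rec <- inject_bursts(bg, list(burst_spec(20, 2.5, "generalized_typical")))
  trig <- run_stream(rec, "oracle", policy = trigger_policy(1.0))
  expect_gte(nrow(trig), 2)
  expect_lte(nrow(trig), 3)
  expect_true(all(trig$eeg_state_truth == "ied"))
  ## causality: triggers strictly follow the causing window end + delays
  ends <- (trig$window_start + 200) / 256
  expect_true(all(trig$trigger_time_s > ends))
  ## refractory spacing holds in every log
  if (nrow(trig) > 1) expect_true(all(diff(trig$trigger_time_s) >= 1.0 - 1e-9))
})

test_that("oracle event-level sensitivity is 1 with zero false positives", {
  co <- generate_cohort(fix_config(duration_s = 300, seed = 43), 2)
  for (rec in co) {
    trig <- run_stream(rec, "oracle")
    expect_equal(sum(trig$eeg_state_truth == "normal"), 0)
    b <- rec$bursts
    long_enough <- b$duration_s >= 200 / 256 + 0.4
    if (any(long_enough)) {
      dm <- detection_metrics(integer(0), integer(0),
                              burst_intervals = cbind(
                                b$onset_s[long_enough],
                                (b$onset_s + b$duration_s)[long_enough]),
                              trigger_times_s = trig$trigger_time_s)
      expect_equal(dm$event_sensitivity, 1)
    }
  }
})

test_that("halving the refractory interval never decreases trigger count", {
  rec <- fix_recording(seed = 47)
  for (refr in c(2, 1, 0.5)) {
    n1 <- nrow(run_stream(rec, "oracle", policy = trigger_policy(refr)))
    n2 <- nrow(run_stream(rec, "oracle", policy = trigger_policy(refr / 2)))
    expect_gte(n2, n1)
  }
})

test_that("car test respects the 1 s deadline and seeds", {
  trig <- data.frame(trigger_time_s = seq_len(400) * 2, window_start = 0L,
                     probability = 1,
                     eeg_state_truth = rep(c("ied", "normal"), 200))
  subj <- subject_model(rt_normal_mean_ms = 550, rt_normal_sd_ms = 100,
                        delta_rt_ms = 150, seed = 5)
  log <- simulate_car_test(trig, subj)
  expect_true(all(is.na(log$response_time_ms) | log$response_time_ms <= 1000))
  expect_true(all(log$crash == log$missed))
  expect_true(all(log$stimulus_onset_s > log$trigger_time_s))
  ## crash fraction higher during bursts when delta_rt is large
  expect_gt(mean(log$crash[log$eeg_state_truth == "ied"]),
            mean(log$crash[log$eeg_state_truth == "normal"]))
  expect_identical(simulate_car_test(trig, subj)$response_time_ms,
                   log$response_time_ms)
})

test_that("null RT shift leaves the state distributions indistinguishable", {
  trig <- data.frame(trigger_time_s = seq_len(400) * 2, window_start = 0L,
                     probability = 1,
                     eeg_state_truth = rep(c("ied", "normal"), each = 200))
  subj <- subject_model(delta_rt_ms = 0, seed = 11)
  log <- simulate_car_test(trig, subj)
  ied <- log$eeg_state_truth == "ied"
  p <- stats::t.test(log$response_time_ms[ied],
                     log$response_time_ms[!ied])$p.value
  expect_gt(p, 0.01)
})

test_that("cognitive probe responses follow the configured probabilities", {
  trig <- data.frame(trigger_time_s = seq_len(1000) * 2, window_start = 0L,
                     probability = 1, eeg_state_truth = "ied")
  subj <- subject_model(iart_miss_prob_ied = 0.25, iart_error_prob_ied = 0.1,
                        seed = 13)
  log <- simulate_iart(trig, subj)
  expect_equal(mean(log$response_class == "missed"), 0.25, tolerance = 0.12)
  ## all probabilities zero -> all correct
  subj0 <- subject_model(iart_error_prob_normal = 0, iart_error_prob_ied = 0,
                         iart_miss_prob_normal = 0, iart_miss_prob_ied = 0)
  log0 <- simulate_iart(trig, subj0)
  expect_true(all(log0$response_class == "correct"))
  ## normal-state error probability near the configured magnitude
  trign <- transform(trig, eeg_state_truth = "normal")
  subjn <- subject_model(iart_error_prob_normal = 0.005, seed = 17)
  logn <- simulate_iart(trign, subjn)
  expect_lt(abs(mean(logn$response_class == "incorrect") - 0.005), 0.01)
})

test_that("event logs serialize to CSV and JSON lines", {
  trig <- data.frame(trigger_time_s = c(2, 4), window_start = 0L,
                     probability = 1, eeg_state_truth = c("ied", "normal"))
  log <- simulate_car_test(trig, subject_model(seed = 1))
  p1 <- file.path(tempdir(), "log.csv")
  p2 <- file.path(tempdir(), "log.jsonl")
  write_event_log(log, p1)
  write_event_log(log, p2)
  back <- utils::read.csv(p1)
  expect_equal(nrow(back), 2)
  expect_equal(length(readLines(p2)), 2)
  unlink(c(p1, p2))
})
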