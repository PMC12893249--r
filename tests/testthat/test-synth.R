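test_that("background generation has the configured size, RMS, and spectrum", {
  cfg <- fix_config(duration_s = 60)
  bg <- generate_background(cfg)
  expect_length(bg$samples, 15360)
  expect_true(all(bg$labels == 0L))
  rms <- sqrt(mean(bg$samples^2))
  expect_gt(rms, 16)
  expect_lt(rms, 24)
  ## spectral mass concentrated in 1-30 Hz
  n <- length(bg$samples)
  spec <- abs(stats::fft(bg$samples))[seq_len(n %/% 2)]^2
  freqs <- (seq_len(n %/% 2) - 1) * cfg$fs_hz / n
  inband <- sum(spec[freqs >= 1 & freqs <= 30])
  expect_gt(inband / sum(spec), 0.9)
})

test_that("background is reproducible under a fixed seed", {
  cfg <- fix_config()
  expect_identical(generate_background(cfg)$samples,
                   generate_background(cfg)$samples)
  cfg2 <- fix_config(seed = 4)
  expect_false(identical(generate_background(cfg)$samples,
                         generate_background(cfg2)$samples))
})

test_that("invalid recording configurations are rejected", {
  expect_error(recording_config(duration_s = 0),
               class = "spikeloop_invalid_configuration")
  expect_error(recording_config(fs_hz = 32),
               class = "spikeloop_invalid_configuration")
  expect_error(recording_config(target_prevalence_per_min = -1),
               class = "spikeloop_invalid_configuration")
})

test_that("burst waveforms have the rounded sample span", {
  wf <- synthesize_burst(burst_spec(0, 0.4, "focal"), 256)
  expect_length(wf, 102)  # round(0.4 * 256)
  wf2 <- synthesize_burst(burst_spec(0, 2, "generalized_typical"), 256)
  expect_length(wf2, 512)
  expect_error(burst_spec(0, 0.3, "focal"), class = "spikeloop_invalid_burst")
  expect_error(burst_spec(0, 11, "focal"), class = "spikeloop_invalid_burst")
})

test_that("a 3 Hz spike-wave burst of 3 s has about nine complexes", {
  spec <- burst_spec(0, 3, "generalized_typical", base_freq_hz = 3,
                     drift_hz = 0)
  wf <- synthesize_burst(spec, 256)
  expect_equal(oracle_count_peaks(wf), 9, tolerance = 0.12)
})

test_that("morphologies differ in amplitude-envelope variability", {
  fs <- 256
  for (seed in 1:5) {
    sp_t <- burst_spec(0, 3, "generalized_typical", 3, 120)
    sp_a <- burst_spec(0, 3, "generalized_atypical", 5, 120)
    cv_t <- burst_envelope_cv(synthesize_burst(sp_t, fs, seed), sp_t, fs)
    cv_a <- burst_envelope_cv(synthesize_burst(sp_a, fs, seed), sp_a, fs)
    expect_lt(cv_t, 0.15)
    expect_gte(cv_a, 0.15)
  }
})

test_that("burst injection sets labels exactly over each burst span", {
  bg <- generate_background(fix_config())
  rec <- inject_bursts(bg, list(burst_spec(10, 2, "focal")))
  ## onset 10 s at 256 Hz -> samples 2561..3072 (1-based)
  expect_equal(which(rec$labels == 1), 2561:3072)
  rec2 <- inject_bursts(bg, list(burst_spec(5, 1, "focal"),
                                 burst_spec(20, 3, "focal")))
  expect_equal(sum(rec2$labels), 256 + 768)
})

test_that("injection rejects overlaps and out-of-bounds bursts", {
  bg <- generate_background(fix_config())
  expect_error(inject_bursts(bg, list(burst_spec(10, 3, "focal"),
                                      burst_spec(11, 2, "focal"))),
               class = "spikeloop_overlap")
  expect_error(inject_bursts(bg, list(burst_spec(59, 2, "focal"))),
               class = "spikeloop_bounds")
  expect_identical(inject_bursts(bg, list()), bg)
})

test_that("label mass equals the sum of rounded burst spans across a cohort", {
  co <- generate_cohort(fix_config(duration_s = 120, seed = 9), 3)
  for (rec in co) {
    expect_equal(sum(rec$labels),
                 sum(round(rec$bursts$duration_s * rec$fs_hz)))
  }
})

test_that("cohort generation is deterministic and prevalence-calibrated", {
  cfg <- fix_config(duration_s = 300, seed = 21)
  a <- generate_cohort(cfg, 2)
  b <- generate_cohort(cfg, 2)
  expect_identical(lapply(a, `[[`, "bursts"), lapply(b, `[[`, "bursts"))
  ## prevalence: >= 100 simulated minutes, empirical rate within 3 SE
  co <- generate_cohort(fix_config(duration_s = 600, seed = 5), 12)
  minutes <- 12 * 10
  n_bursts <- sum(vapply(co, function(r) nrow(r$bursts), 0L))
  se <- sqrt(2.2 * minutes) / minutes
  expect_lt(abs(n_bursts / minutes - 2.2), 3 * se)
})

test_that("zero prevalence yields burst-free recordings", {
  co <- generate_cohort(fix_config(target_prevalence_per_min = 0), 2)
  expect_true(all(vapply(co, function(r) nrow(r$bursts) == 0, TRUE)))
})

test_that("band-power separates typical bursts from background (AUROC > .9)", {
  co <- generate_cohort(fix_config(duration_s = 300, seed = 31), 4)
  ws <- lapply(co, frame_windows)
  lab <- unlist(lapply(ws, `[[`, "label"))
  pow <- unlist(lapply(ws, band_power))
  roc <- pROC::roc(lab, pow, quiet = TRUE, direction = "<", levels = c(0, 1))
  expect_gt(as.numeric(pROC::auc(roc)), 0.9)
})
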