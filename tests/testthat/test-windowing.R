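test_that("window/step durations match the reference geometry", {
  expect_equal(unname(window_duration_ms(windowing_params())),
               c(781, 195))
  expect_equal(unname(window_duration_ms(
    windowing_params(window_len = 256, step = 256))[1]), 1000)
})

test_that("framing produces the expected window count and starts", {
  rec <- new_rec <- structure(list(samples = rnorm(300), fs_hz = 256,
                                   labels = integer(300),
                                   bursts = data.frame(),
                                   channel_name = "T"),
                              class = "labeled_recording")
  ws <- frame_windows(rec)
  expect_equal(length(ws$starts), 3)
  expect_equal(ws$starts, c(0L, 50L, 100L))
  rec200 <- rec
  rec200$samples <- rec200$samples[1:200]
  rec200$labels <- integer(200)
  expect_equal(length(frame_windows(rec200)$starts), 1)
  rec199 <- rec
  rec199$samples <- rec199$samples[1:199]
  rec199$labels <- integer(199)
  expect_error(frame_windows(rec199), class = "spikeloop_insufficient_data")
})

test_that("framing arithmetic holds under fuzzing", {
  set.seed(42)
  for (i in 1:50) {
    L <- sample(50:300, 1)
    S <- sample(seq_len(L), 1)
    N <- L + sample(0:1000, 1)
    rec <- structure(list(samples = numeric(N), fs_hz = 256,
                          labels = integer(N), bursts = data.frame(),
                          channel_name = "T"), class = "labeled_recording")
    ws <- frame_windows(rec, windowing_params(window_len = L, step = S,
                                              positive_threshold = L))
    expect_equal(length(ws$starts), (N - L) %/% S + 1)
    expect_true(all(ws$starts + L <= N))
  }
})

test_that("window label follows the 150-sample majority rule exactly", {
  n <- 400
  labels <- integer(n)
  labels[101:250] <- 1L       # window [51, 250] has exactly 150 positives
  rec <- structure(list(samples = rnorm(n), fs_hz = 256, labels = labels,
                        bursts = data.frame(), channel_name = "T"),
                   class = "labeled_recording")
  ws <- frame_windows(rec)
  w2 <- window_frame(ws, 2)  # start 50 -> samples 51..250
  expect_equal(w2$n_positive, 150L)
  expect_equal(w2$label, 1L)
  ## flip one labeled sample across the boundary: 149 positives -> label 0
  labels2 <- labels
  labels2[250] <- 0L
  rec2 <- rec
  rec2$labels <- labels2
  w2b <- window_frame(frame_windows(rec2), 2)
  expect_equal(w2b$n_positive, 149L)
  expect_equal(w2b$label, 0L)
})

test_that("non-reference sampling rates are resampled before framing", {
  cfg <- recording_config(duration_s = 10, fs_hz = 128, seed = 2,
                          noise_spectrum = list(slope = 1, band = c(0.5, 30),
                                                alpha_freq = 10,
                                                alpha_width = 1.5,
                                                alpha_weight = 1.5))
  rec <- generate_background(cfg)
  ws <- frame_windows(rec, windowing_params())
  expect_equal(length(ws$starts), (10 * 256 - 200) %/% 50 + 1)
})

test_that("EDF round-trip preserves samples, labels, and annotations", {
  rec <- fix_recording()
  path <- file.path(tempdir(), "roundtrip.edf")
  write_recording_edf(rec, path)
  back <- read_recording_edf(path)
  expect_equal(back$fs_hz, 256)
  expect_equal(length(back$samples), length(rec$samples))
  ## 16-bit quantization: relative error bounded by the amplitude range
  expect_lt(max(abs(back$samples - rec$samples)),
            diff(range(rec$samples)) / 65535 * 1.01)
  expect_identical(back$labels, rec$labels)
  expect_equal(back$bursts$onset_s, rec$bursts$onset_s)
  expect_equal(back$bursts$morphology, rec$bursts$morphology)
  unlink(c(path, paste0(path, c(".annotations.csv", ".labels.csv"))))
})

test_that("two-column CSV reader infers the sampling frequency", {
  d <- data.frame(time_s = (0:511) / 256, microvolts = rnorm(512))
  path <- file.path(tempdir(), "rec.csv")
  utils::write.csv(d, path, row.names = FALSE)
  rec <- read_recording_csv(path)
  expect_equal(rec$fs_hz, 256)
  expect_equal(rec$samples, d$microvolts)
  unlink(path)
})
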