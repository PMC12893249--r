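## ---- sliding-window framing of labeled recordings --------------------------

#' Windowing parameters
#'
#' Sliding-window geometry for framing a recording. The defaults (200-sample
#' windows advanced by 50 samples at 256 Hz, i.e. 781 ms windows with 195 ms
#' steps and about 600 ms overlap) match the real-time deployment this
#' package emulates. A window is labeled as an IED-burst when at least
#' `positive_threshold` of its samples carry the per-sample burst label.
#'
#' @param window_len Window length in samples (default 200).
#' @param step Step between window starts in samples (default 50).
#' @param fs_hz Sampling frequency the geometry assumes (default 256).
#' @param positive_threshold Minimum label-1 samples for a positive window
#'   (default 150).
#' @return An object of class `windowing_params`.
#' @export
windowing_params <- function(window_len = 200L, step = 50L, fs_hz = 256,
                             positive_threshold = 150L) {
  if (step <= 0 || step > window_len) {
    sl_stop("step must satisfy 0 < step <= window_len",
            "spikeloop_invalid_configuration")
  }
  if (positive_threshold > window_len) {
    sl_stop("positive_threshold must be <= window_len",
            "spikeloop_invalid_configuration")
  }
  structure(list(window_len = as.integer(window_len), step = as.integer(step),
                 fs_hz = fs_hz,
                 positive_threshold = as.integer(positive_threshold)),
            class = "windowing_params")
}

#' Window and step duration in milliseconds
#'
#' @param params A [windowing_params()].
#' @return Named numeric vector with `window_ms` and `step_ms`, each
#'   `floor(len / fs * 1000)`; the defaults give 781 and 195 ms at 256 Hz.
#' @export
window_duration_ms <- function(params) {
  if (params$fs_hz <= 0) {
    sl_stop("fs_hz must be > 0", "spikeloop_invalid_configuration")
  }
  c(window_ms = floor(params$window_len / params$fs_hz * 1000),
    step_ms = floor(params$step / params$fs_hz * 1000))
}

#' Resample a recording to a target sampling frequency
#'
#' Polyphase resampling of the samples; labels are carried over by
#' nearest-neighbor index mapping so burst spans are preserved.
#'
#' @param recording A `labeled_recording`.
#' @param fs_target Target sampling frequency in Hz.
#' @return A `labeled_recording` at `fs_target`.
#' @export
resample_recording <- function(recording, fs_target) {
  if (recording$fs_hz == fs_target) return(recording)
  gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
  p <- round(fs_target * 1000)
  q <- round(recording$fs_hz * 1000)
  g <- gcd(p, q)
  x <- signal::resample(recording$samples, p / g, q / g)
  n_new <- round(length(recording$samples) * fs_target / recording$fs_hz)
  x <- x[seq_len(min(n_new, length(x)))]
  src <- pmin(length(recording$labels),
              pmax(1, round(seq_along(x) * recording$fs_hz / fs_target)))
  new_labeled_recording(x, fs_target, recording$labels[src],
                        recording$bursts, recording$channel_name)
}

#' Frame a recording into overlapping windows
#'
#' Cuts the recording into windows starting at 0, `step`, `2*step`, ...
#' samples; a trailing partial window is discarded. Each window carries the
#' count of label-1 samples and the binary window label (positive iff
#' `n_positive >= positive_threshold`). Recordings at a different sampling
#' frequency than `params$fs_hz` are resampled first.
#'
#' @param recording A `labeled_recording`.
#' @param params A [windowing_params()].
#' @return An object of class `window_set`: list with `starts` (0-based
#'   sample offsets), `values` (window_len x n_windows matrix), `n_positive`,
#'   `label`, and the framing parameters.
#' @export
frame_windows <- function(recording, params = windowing_params()) {
  if (recording$fs_hz != params$fs_hz) {
    recording <- resample_recording(recording, params$fs_hz)
  }
  n <- length(recording$samples)
  L <- params$window_len
  S <- params$step
  if (n < L) {
    sl_stop("recording shorter than one window", "spikeloop_insufficient_data")
  }
  n_win <- (n - L) %/% S + 1
  starts <- (seq_len(n_win) - 1L) * S          # 0-based
  idx <- outer(seq_len(L), starts, `+`)        # L x n_win sample indices
  values <- matrix(recording$samples[idx], nrow = L)
  n_positive <- as.integer(colSums(matrix(recording$labels[idx], nrow = L)))
  structure(list(starts = starts, values = values, n_positive = n_positive,
                 label = as.integer(n_positive >= params$positive_threshold),
                 params = params),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of %d samples (step %d), %d positive\n",
              length(x$starts), x$params$window_len, x$params$step,
              sum(x$label)))
  invisible(x)
}

#' Extract one window frame
#'
#' @param windows A `window_set`.
#' @param i Window index (1-based).
#' @return List with `start_index`, `values`, `n_positive`, `label`.
#' @export
window_frame <- function(windows, i) {
  list(start_index = windows$starts[i], values = windows$values[, i],
       n_positive = windows$n_positive[i], label = windows$label[i])
}
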