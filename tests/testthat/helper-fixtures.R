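## shared small fixtures, built in code at load time

fix_config <- function(duration_s = 60, seed = 3, ...) {
  recording_config(duration_s = duration_s, seed = seed, ...)
}

## one 60 s recording with two known bursts at fixed positions
fix_recording <- function(seed = 3) {
  bg <- generate_background(fix_config(seed = seed))
  inject_bursts(bg, list(
    burst_spec(10, 2, "generalized_typical", 3, 120),
    burst_spec(30, 3, "generalized_atypical", 5, 150)),
    seed = seed)
}

## brute-force MTF oracle: literal per-definition implementation, kept
## independent of the package's vectorized path
oracle_mtf <- function(values, n_bins) {
  n <- length(values)
  ## right-closed empirical quantile bins via the ECDF, ties share a bin
  r <- vapply(values, function(v) sum(values <= v), 0L)
  bins <- pmin(ceiling(r / n * n_bins), n_bins)
  W <- matrix(0, n_bins, n_bins)
  for (t in seq_len(n - 1)) {
    W[bins[t], bins[t + 1]] <- W[bins[t], bins[t + 1]] + 1
  }
  for (a in seq_len(n_bins)) {
    s <- sum(W[a, ])
    if (s > 0) W[a, ] <- W[a, ] / s
  }
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      M[i, j] <- W[bins[i], bins[j]]
    }
  }
  M
}

## brute-force peak counter: strict local maxima above half the global max
oracle_count_peaks <- function(x) {
  thr <- max(x) / 2
  sum(vapply(2:(length(x) - 1), function(i) {
    x[i] > x[i - 1] && x[i] > x[i + 1] && x[i] > thr
  }, TRUE))
}
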