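## ---- synthetic single-channel EEG with injected IED-bursts -----------------

#' Burst specification
#'
#' Describes one interictal epileptiform discharge (IED) burst to be injected
#' into a recording: a series of epileptiform potentials of 0.4--10 s with
#' near-constant frequency (instantaneous-frequency drift below 1 Hz over the
#' burst).
#'
#' @param onset_s Onset in seconds from recording start (>= 0).
#' @param duration_s Duration in seconds, in `[0.4, 10]`.
#' @param morphology One of `"generalized_typical"` (classically configured
#'   spike--waves, well organized, near-constant amplitude),
#'   `"generalized_atypical"` (blunter spike--waves and sharp theta, variable
#'   amplitude over time), `"focal"` (sharp transients, morphology-free
#'   definition).
#' @param base_freq_hz Dominant discharge frequency in Hz.
#' @param amplitude_uv Peak amplitude in microvolts.
#' @param drift_hz Total within-burst frequency drift in Hz; must be < 1.
#' @return An object of class `burst_spec`.
#' @export
burst_spec <- function(onset_s, duration_s, morphology = c(
                         "generalized_typical", "generalized_atypical", "focal"),
                       base_freq_hz = 3, amplitude_uv = 120, drift_hz = 0.5) {
  morphology <- match.arg(morphology)
  if (!is.numeric(duration_s) || duration_s < 0.4 || duration_s > 10) {
    sl_stop("burst duration must lie in [0.4, 10] s", "spikeloop_invalid_burst")
  }
  if (onset_s < 0) sl_stop("burst onset must be >= 0", "spikeloop_invalid_burst")
  if (abs(drift_hz) >= 1) {
    sl_stop("within-burst frequency drift must be < 1 Hz",
            "spikeloop_invalid_burst")
  }
  structure(list(onset_s = onset_s, duration_s = duration_s,
                 morphology = morphology, base_freq_hz = base_freq_hz,
                 amplitude_uv = amplitude_uv, drift_hz = drift_hz),
            class = "burst_spec")
}

#' Recording configuration
#'
#' Parameters of one synthetic EEG recording: duration, sampling frequency,
#' expected burst prevalence, and the composition of the background activity.
#'
#' @param duration_s Recording duration in seconds (> 0).
#' @param fs_hz Sampling frequency in Hz (>= 64; reference 256).
#' @param target_prevalence_per_min Expected IED-bursts per minute (>= 0);
#'   the pilot cohort this emulates ran at 2.2/min.
#' @param background_amplitude_uv Background RMS amplitude in microvolts.
#' @param noise_spectrum List with `slope` (power-law exponent of the 1/f
#'   background), `band` (length-2 passband in Hz), `alpha_freq`,
#'   `alpha_width`, `alpha_weight` (posterior-rhythm bump).
#' @param seed Integer seed; all randomness derives from it.
#' @return An object of class `recording_config`.
#' @export
recording_config <- function(duration_s = 600, fs_hz = 256,
                             target_prevalence_per_min = 2.2,
                             background_amplitude_uv = 20,
                             noise_spectrum = list(slope = 1,
                                                   band = c(0.5, 30),
                                                   alpha_freq = 10,
                                                   alpha_width = 1.5,
                                                   alpha_weight = 1.5),
                             seed = 1L) {
  if (!is.numeric(duration_s) || length(duration_s) != 1 || duration_s <= 0 ||
      !is.numeric(fs_hz) || fs_hz < 64) {
    sl_stop("duration_s must be > 0 and fs_hz >= 64",
            "spikeloop_invalid_configuration")
  }
  if (target_prevalence_per_min < 0) {
    sl_stop("target_prevalence_per_min must be >= 0",
            "spikeloop_invalid_configuration")
  }
  if (fs_hz <= 2 * max(noise_spectrum$band)) {
    sl_stop("fs_hz must exceed twice the highest synthesized frequency",
            "spikeloop_invalid_configuration")
  }
  structure(list(duration_s = duration_s, fs_hz = fs_hz,
                 target_prevalence_per_min = target_prevalence_per_min,
                 background_amplitude_uv = background_amplitude_uv,
                 noise_spectrum = noise_spectrum, seed = as.integer(seed)),
            class = "recording_config")
}

new_labeled_recording <- function(samples, fs_hz, labels, bursts,
                                  channel_name = "F3-C3") {
  stopifnot(length(samples) == length(labels))
  structure(list(samples = as.numeric(samples), fs_hz = fs_hz,
                 labels = as.integer(labels), bursts = bursts,
                 channel_name = channel_name),
            class = "labeled_recording")
}

empty_burst_table <- function() {
  data.frame(onset_s = numeric(0), duration_s = numeric(0),
             morphology = character(0), base_freq_hz = numeric(0),
             amplitude_uv = numeric(0), drift_hz = numeric(0))
}

#' @export
print.labeled_recording <- function(x, ...) {
  cat(sprintf(
    "<labeled_recording> %s: %d samples @ %g Hz (%.1f min), %d burst(s), %d labeled sample(s)\n",
    x$channel_name, length(x$samples), x$fs_hz,
    length(x$samples) / x$fs_hz / 60, nrow(x$bursts), sum(x$labels)))
  invisible(x)
}

#' Generate background EEG
#'
#' Produces a burst-free recording of colored background noise: a 1/f-weighted
#' broadband component band-limited to the configured passband plus a
#' narrow-band 8--12 Hz rhythmic component, scaled to the configured RMS
#' amplitude. All labels are 0.
#'
#' @param config A [recording_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A `labeled_recording` with all labels 0.
#' @export
generate_background <- function(config, seed = config$seed) {
  if (!inherits(config, "recording_config")) {
    sl_stop("config must be a recording_config",
            "spikeloop_invalid_configuration")
  }
  n <- round_half_up(config$duration_s * config$fs_hz)
  ns <- config$noise_spectrum
  x <- with_seed(derive_seed(seed, "background"), {
    w <- stats::rnorm(n)
    ## frequency-domain shaping: 1/f^slope magnitude inside the passband,
    ## smooth roll-off above, plus a Gaussian alpha bump
    freqs <- seq(0, config$fs_hz / 2, length.out = floor(n / 2) + 1)
    gain <- numeric(length(freqs))
    inband <- freqs >= ns$band[1] & freqs <= ns$band[2]
    gain[inband] <- 1 / sqrt(pmax(freqs[inband], 1)^ns$slope)
    above <- freqs > ns$band[2]
    gain[above] <- 1 / sqrt(ns$band[2]^ns$slope) *
      exp(-(freqs[above] - ns$band[2]) / 3)
    gain <- gain + ns$alpha_weight * mean(gain[inband]) *
      exp(-0.5 * ((freqs - ns$alpha_freq) / ns$alpha_width)^2)
    W <- stats::fft(w)
    full_gain <- c(gain, rev(gain[2:(n - length(freqs) + 1)]))
    Re(stats::fft(W * full_gain, inverse = TRUE)) / n
  })
  x <- x - mean(x)
  x <- x / sqrt(mean(x^2)) * config$background_amplitude_uv
  new_labeled_recording(x, config$fs_hz, integer(length(x)),
                        empty_burst_table())
}

## periodic cycle shape: narrow gaussian spike + aftergoing slow wave.
## `c` is the within-cycle position in [0, 1).
cycle_shape <- function(c, spike_width, wave_amp) {
  exp(-0.5 * ((c - 0.2) / spike_width)^2) - wave_amp * sin(2 * pi * (c - 0.2))
}

#' Synthesize one IED-burst waveform
#'
#' Renders a burst as a train of spike--wave cycles whose instantaneous
#' frequency drifts linearly by less than 1 Hz across the burst. Morphologies
#' differ in spike sharpness and amplitude-envelope variability: the
#' generalized typical form keeps a near-constant envelope (coefficient of
#' variation of per-cycle peaks < 0.15), the generalized atypical form has a
#' slowly modulated envelope (CV >= 0.15) and an added sharp-theta component,
#' and the focal form is a sharp-transient train with mild modulation.
#'
#' @param spec A [burst_spec()].
#' @param fs_hz Sampling frequency in Hz.
#' @param seed Integer seed for the envelope/phase jitter.
#' @return Numeric waveform of `round(duration_s * fs_hz)` samples (half-up),
#'   peak absolute amplitude equal to `spec$amplitude_uv`.
#' @export
synthesize_burst <- function(spec, fs_hz, seed = 1L) {
  if (!inherits(spec, "burst_spec")) {
    spec <- do.call(burst_spec, as.list(spec)) # validates duration etc.
  }
  if (fs_hz <= 2 * (spec$base_freq_hz + 1)) {
    sl_stop("fs_hz too low for the requested discharge frequency",
            "spikeloop_invalid_burst")
  }
  n <- round_half_up(spec$duration_s * fs_hz)
  t <- (seq_len(n) - 1) / fs_hz
  ## linear instantaneous-frequency drift, total magnitude spec$drift_hz < 1 Hz
  f_inst <- spec$base_freq_hz + spec$drift_hz * (t / spec$duration_s - 0.5)
  phase <- cumsum(f_inst) / fs_hz          # cycles
  cpos <- phase %% 1
  with_seed(derive_seed(seed, "burst", spec$morphology), {
    env_phase <- stats::runif(1, 0, 2 * pi)
    base <- switch(spec$morphology,
      generalized_typical = {
        env <- rep(1, n)
        cycle_shape(cpos, spike_width = 0.045, wave_amp = 0.45) * env
      },
      generalized_atypical = {
        ## variable amplitude over time: slow sinusoidal envelope, CV ~ 0.3
        env <- 1 + 0.45 * sin(2 * pi * t / spec$duration_s *
                                stats::runif(1, 1, 2.5) + env_phase)
        blunt <- cycle_shape(cpos, spike_width = 0.10, wave_amp = 0.35)
        theta <- 0.25 * sin(2 * pi * (spec$base_freq_hz + 1.5) * t)
        (blunt + theta) * env
      },
      focal = {
        env <- 1 + 0.12 * sin(2 * pi * t / spec$duration_s + env_phase)
        cycle_shape(cpos, spike_width = 0.06, wave_amp = 0.30) * env
      })
    base / max(abs(base)) * spec$amplitude_uv
  })
}

## per-cycle peak amplitudes of a synthesized burst; used for envelope CV
## checks and exported for diagnostics
#' Coefficient of variation of a burst's per-cycle peak amplitudes
#' @param waveform Burst waveform from [synthesize_burst()].
#' @param spec The generating [burst_spec()].
#' @param fs_hz Sampling frequency in Hz.
#' @return CV (sd/mean) of per-cycle absolute peaks.
#' @export
burst_envelope_cv <- function(waveform, spec, fs_hz) {
  n <- length(waveform)
  t <- (seq_len(n) - 1) / fs_hz
  f_inst <- spec$base_freq_hz + spec$drift_hz * (t / spec$duration_s - 0.5)
  cyc <- floor(cumsum(f_inst) / fs_hz)
  peaks <- tapply(abs(waveform), cyc, max)
  peaks <- peaks[seq_len(max(1, length(peaks) - 1))]  # drop partial last cycle
  if (length(peaks) < 2) return(0)
  stats::sd(peaks) / mean(peaks)
}

#' Inject bursts into a background recording
#'
#' Adds each burst waveform to the background at its onset and sets the
#' per-sample labels to 1 exactly over each burst's sample span
#' (`round(duration_s * fs)` samples, half-up).
#'
#' @param background A `labeled_recording` (typically burst-free).
#' @param specs List of [burst_spec()] objects; must be non-overlapping and
#'   inside the recording span.
#' @param seed Integer seed for waveform jitter.
#' @return A `labeled_recording` with samples, labels, and the burst table
#'   populated.
#' @export
inject_bursts <- function(background, specs, seed = 1L) {
  if (length(specs) == 0) return(background)
  fs <- background$fs_hz
  n <- length(background$samples)
  starts <- vapply(specs, function(s) round_half_up(s$onset_s * fs) + 1, 0)
  lens <- vapply(specs, function(s) round_half_up(s$duration_s * fs), 0)
  ends <- starts + lens - 1
  ord <- order(starts)
  if (any(ends[ord][-length(ord)] >= starts[ord][-1])) {
    sl_stop("burst specs overlap", "spikeloop_overlap")
  }
  if (any(ends > n) || any(starts < 1)) {
    sl_stop("burst extends past the recording span", "spikeloop_bounds")
  }
  samples <- background$samples
  labels <- background$labels
  for (i in seq_along(specs)) {
    wf <- synthesize_burst(specs[[i]], fs, seed = derive_seed(seed, "inj", i))
    idx <- starts[i]:ends[i]
    samples[idx] <- samples[idx] + wf
    labels[idx] <- 1L
  }
  tab <- do.call(rbind, lapply(specs, function(s)
    data.frame(onset_s = s$onset_s, duration_s = s$duration_s,
               morphology = s$morphology, base_freq_hz = s$base_freq_hz,
               amplitude_uv = s$amplitude_uv, drift_hz = s$drift_hz)))
  tab <- rbind(background$bursts, tab)
  tab <- tab[order(tab$onset_s), , drop = FALSE]
  rownames(tab) <- NULL
  new_labeled_recording(samples, fs, labels, tab, background$channel_name)
}

## draw one burst's free parameters from the default cohort distributions
draw_burst_params <- function() {
  morph <- sample(c("generalized_typical", "generalized_atypical", "focal"),
                  1, prob = c(0.4, 0.3, 0.3))
  ## log-uniform durations on [0.4 s, 4 s] (hard cap 10 s), anchored to the
  ## 0.7--2.6 s per-session mean burst durations of the emulated cohort
  dur <- exp(stats::runif(1, log(0.4), log(4)))
  freq <- switch(morph,
                 generalized_typical = stats::runif(1, 2.5, 4),
                 generalized_atypical = stats::runif(1, 4, 6.5),
                 focal = stats::runif(1, 3, 6))
  list(duration_s = min(dur, 10), morphology = morph, base_freq_hz = freq,
       amplitude_uv = stats::runif(1, 80, 200),
       drift_hz = stats::runif(1, -0.4, 0.4))
}

#' Generate a cohort of labeled recordings
#'
#' Draws burst onsets from a homogeneous point process at the configured
#' prevalence (rejecting overlaps with bounded retries) and burst duration,
#' morphology, frequency, and amplitude from the default distributions, then
#' injects them into freshly generated background.
#'
#' @param config A [recording_config()].
#' @param n_recordings Number of recordings (>= 1).
#' @param seed Integer master seed; the run is fully reproducible from it.
#' @return List of `labeled_recording` objects.
#' @export
generate_cohort <- function(config, n_recordings, seed = config$seed) {
  if (!is_count(n_recordings) || n_recordings < 1) {
    sl_stop("n_recordings must be >= 1", "spikeloop_invalid_configuration")
  }
  lapply(seq_len(n_recordings), function(r) {
    rec_seed <- derive_seed(seed, "rec", r)
    bg <- generate_background(config, seed = rec_seed)
    specs <- with_seed(derive_seed(rec_seed, "bursts"), {
      n_b <- stats::rpois(1, config$target_prevalence_per_min *
                               config$duration_s / 60)
      placed <- list()
      occupied <- matrix(numeric(0), ncol = 2)
      for (b in seq_len(n_b)) {
        par <- draw_burst_params()
        ok <- FALSE
        for (try in 1:200) {
          onset <- stats::runif(1, 0, config$duration_s - par$duration_s)
          if (nrow(occupied) == 0 ||
              all(onset + par$duration_s <= occupied[, 1] |
                  onset >= occupied[, 2])) {
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          sl_stop("could not place bursts at the requested prevalence",
                  "spikeloop_placement")
        }
        occupied <- rbind(occupied, c(onset, onset + par$duration_s))
        placed[[b]] <- burst_spec(onset_s = onset,
                                  duration_s = par$duration_s,
                                  morphology = par$morphology,
                                  base_freq_hz = par$base_freq_hz,
                                  amplitude_uv = par$amplitude_uv,
                                  drift_hz = par$drift_hz)
      }
      placed
    })
    inject_bursts(bg, specs, seed = derive_seed(rec_seed, "wave"))
  })
}
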