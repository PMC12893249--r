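## ---- minimal single-channel EDF and CSV recording I/O ----------------------
##
## EDF: 256-byte fixed header + 256 bytes per signal header, then 1-second
## data records of little-endian int16 samples mapped through the
## physical/digital calibration. One signal only; the last record is
## zero-padded when the recording length is not a whole number of seconds.

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write a labeled recording as EDF plus sidecar annotations
#'
#' Writes the samples as a one-signal EDF file (physical dimension uV,
#' sampling frequency in the header), a CSV sidecar with one row per burst
#' (`onset_s`, `duration_s`, `morphology`), and a per-sample label CSV.
#'
#' @param recording A `labeled_recording`.
#' @param path Output EDF path; sidecars get `.annotations.csv` and
#'   `.labels.csv` suffixes next to it.
#' @return `path`, invisibly.
#' @export
write_recording_edf <- function(recording, path) {
  x <- recording$samples
  fs <- recording$fs_hz
  if (fs != round(fs)) {
    sl_stop("EDF writer requires an integer sampling frequency",
            "spikeloop_io")
  }
  n_rec <- ceiling(length(x) / fs)
  x_pad <- c(x, numeric(n_rec * fs - length(x)))
  phys_min <- min(x_pad); phys_max <- max(x_pad)
  if (phys_max <= phys_min) phys_max <- phys_min + 1
  dig_min <- -32768; dig_max <- 32767
  dig <- as.integer(round((x_pad - phys_min) / (phys_max - phys_min) *
                            (dig_max - dig_min) + dig_min))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),                       # version
    pad_field("X X X X", 80),                # patient id (anonymous)
    pad_field("Startdate X X X X", 80),      # recording id
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 + 256, 8),                 # header bytes (1 signal)
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field("1", 8),                       # record duration, s
    pad_field("1", 4))                       # number of signals
  sig <- paste0(
    pad_field(recording$channel_name, 16),
    pad_field("AgAgCl scalp electrode", 80),
    pad_field("uV", 8),
    pad_field(format(phys_min, digits = 7), 8),
    pad_field(format(phys_max, digits = 7), 8),
    pad_field(dig_min, 8), pad_field(dig_max, 8),
    pad_field("", 80),                       # prefiltering
    pad_field(fs, 8),                        # samples per record
    pad_field("", 32))
  writeChar(paste0(hdr, sig), con, eos = NULL)
  writeBin(dig, con, size = 2, endian = "little")
  utils::write.csv(recording$bursts[, c("onset_s", "duration_s", "morphology")],
                   paste0(path, ".annotations.csv"), row.names = FALSE)
  utils::write.csv(data.frame(label = recording$labels),
                   paste0(path, ".labels.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a recording from EDF
#'
#' Reads a one-signal EDF written by [write_recording_edf()] (or any
#' single-channel EDF with integer-second records). Burst annotations and
#' per-sample labels are restored from the sidecar CSVs when present.
#'
#' @param path EDF file path.
#' @return A `labeled_recording`.
#' @export
read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  n_rec <- as.integer(substr(hdr, 237, 244))
  rec_dur <- as.numeric(substr(hdr, 245, 252))
  n_sig <- as.integer(substr(hdr, 253, 256))
  if (is.na(n_sig) || n_sig != 1) {
    sl_stop("only single-signal EDF files are supported", "spikeloop_io")
  }
  sig <- readChar(con, 256, useBytes = TRUE)
  label <- trimws(substr(sig, 1, 16))
  phys_min <- as.numeric(substr(sig, 105, 112))
  phys_max <- as.numeric(substr(sig, 113, 120))
  dig_min <- as.numeric(substr(sig, 121, 128))
  dig_max <- as.numeric(substr(sig, 129, 136))
  spr <- as.integer(substr(sig, 217, 224))
  fs <- spr / rec_dur
  dig <- readBin(con, "integer", n = n_rec * spr, size = 2, signed = TRUE,
                 endian = "little")
  x <- (dig - dig_min) / (dig_max - dig_min) * (phys_max - phys_min) + phys_min
  ann_path <- paste0(path, ".annotations.csv")
  lab_path <- paste0(path, ".labels.csv")
  bursts <- if (file.exists(ann_path)) {
    a <- utils::read.csv(ann_path)
    cbind(a, base_freq_hz = NA_real_, amplitude_uv = NA_real_,
          drift_hz = NA_real_)[, names(empty_burst_table())]
  } else {
    empty_burst_table()
  }
  labels <- if (file.exists(lab_path)) {
    utils::read.csv(lab_path)$label
  } else {
    integer(length(x))
  }
  if (length(labels) < length(x)) {   # zero-padded final record
    x <- x[seq_along(labels)]
  }
  new_labeled_recording(x, fs, labels, bursts, channel_name = label)
}

#' Read a recording from a two-column CSV
#'
#' Accepts a CSV with columns `time_s` and `microvolts`; the sampling
#' frequency is inferred from the median time step unless supplied.
#'
#' @param path CSV file path.
#' @param fs_hz Optional sampling frequency override.
#' @return A `labeled_recording` with all labels 0.
#' @export
read_recording_csv <- function(path, fs_hz = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "microvolts") %in% names(d))) {
    sl_stop("CSV must have columns time_s and microvolts", "spikeloop_io")
  }
  if (is.null(fs_hz)) {
    fs_hz <- 1 / stats::median(diff(d$time_s))
    fs_hz <- round(fs_hz)
  }
  new_labeled_recording(d$microvolts, fs_hz, integer(nrow(d)),
                        empty_burst_table())
}
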