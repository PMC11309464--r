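# Minimal EDF (European Data Format, 16-bit) I/O and BIDS-style events files.
# Only the subset of EDF needed to exchange the simulator's recordings is
# implemented: one data record per second, identical sampling rate on every
# signal, physical units in microvolts.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Serializes an [new_recording()] object as 16-bit EDF with physical units in
#' microvolts and one-second data records. The recording is zero-padded to a
#' whole number of records.
#'
#' @param recording an `eeg_recording`.
#' @param path output file path.
#' @param patient,recording_id free-text EDF header fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, patient = "X", recording_id = "synthetic") {
  fs <- recording$fs
  if (fs != round(fs)) stopf("EDF export requires an integer sampling rate")
  fs <- as.integer(fs)
  data <- recording$data
  ns <- nrow(data)
  n_rec <- as.integer(ceiling(ncol(data) / fs))
  if (ncol(data) < n_rec * fs) {
    data <- cbind(data, matrix(0, ns, n_rec * fs - ncol(data)))
  }
  # round the physical range to the header's printed precision so that the
  # scale used for quantization matches what a reader reconstructs
  phys_max <- round(pmax(apply(abs(data), 1, max), 1) * 1.0001, 1) + 0.1
  dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad(patient, 80), edf_pad(recording_id, 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad("1", 8), edf_pad(ns, 4)
  )
  sig <- paste0(
    paste(edf_pad(recording$channels, 16), collapse = ""),
    paste(rep(edf_pad("simulated", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(edf_pad(sprintf("%.1f", -phys_max), 8), collapse = ""),
    paste(edf_pad(sprintf("%.1f", phys_max), 8), collapse = ""),
    paste(rep(edf_pad(-dig_max - 1, 8), ns), collapse = ""),
    paste(rep(edf_pad(dig_max, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(fs, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = "")
  )
  writeChar(paste0(hdr, sig), con, eos = NULL, useBytes = TRUE)
  scale <- dig_max / phys_max
  for (r in seq_len(n_rec)) {
    block <- data[, ((r - 1) * fs + 1):(r * fs), drop = FALSE]
    dig <- round(block * scale)
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path EDF file path.
#' @return an `eeg_recording` in microvolts.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8) # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80) # transducer
  for (i in seq_len(ns)) rd(8)  # unit
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80) # prefilter
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1) stopf("mixed sampling rates not supported")
  fs <- spr[1] / rec_dur
  data <- matrix(0, ns, n_rec * spr[1])
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = ns * spr[1], size = 2,
                   endian = "little", signed = TRUE)
    block <- matrix(raw, nrow = spr[1], ncol = ns)
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    data[, cols] <- t(block) * scale + (phys_min - dig_min * scale)
  }
  new_recording(data, fs, labels)
}

#' Write a BIDS-style events file
#'
#' Tab-separated events table with onset (s), duration (s), trial_type,
#' response and response_time (s) columns, suitable for pairing with an EDF
#' export.
#'
#' @param events data.frame with at least `onset_s`, `duration_s`, `trial_type`;
#'   optional `correct` (logical) and `rt_s`.
#' @param path output path (conventionally `*_events.tsv`).
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  out <- data.frame(
    onset = events$onset_s,
    duration = events$duration_s,
    trial_type = as.character(events$trial_type),
    response = if ("correct" %in% names(events)) {
      ifelse(is.na(events$correct), "n/a", ifelse(events$correct, "correct", "incorrect"))
    } else "n/a",
    response_time = if ("rt_s" %in% names(events)) {
      ifelse(is.na(events$rt_s), "n/a", format(events$rt_s, digits = 6))
    } else "n/a",
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BIDS-style events file
#'
#' @param path events TSV path.
#' @return data.frame with `onset_s`, `duration_s`, `trial_type`, `correct`, `rt_s`.
#' @export
read_events_tsv <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           na.strings = "n/a", stringsAsFactors = FALSE)
  data.frame(
    onset_s = raw$onset,
    duration_s = raw$duration,
    trial_type = raw$trial_type,
    correct = if ("response" %in% names(raw)) raw$response == "correct" else NA,
    rt_s = if ("response_time" %in% names(raw)) as.numeric(raw$response_time) else NA_real_,
    stringsAsFactors = FALSE
  )
}
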