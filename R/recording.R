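#' Continuous EEG recording container
#'
#' Lightweight container for continuous multichannel EEG: a channels x samples
#' matrix in microvolts plus the sampling rate, channel labels and optional
#' event annotations.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_labels character vector of unique channel labels; defaults to
#'   `rownames(data)`.
#' @param annotations optional data.frame of events (see [epoch_recording()]).
#' @return an object of class `eeg_recording`.
#' @export
new_recording <- function(data, fs, channel_labels = rownames(data),
                          annotations = NULL) {
  if (!is.matrix(data)) data <- as.matrix(data)
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(nrow(data)))
  }
  if (anyDuplicated(channel_labels)) stopf("channel labels must be unique")
  if (length(channel_labels) != nrow(data)) {
    stopf("channel_labels length (%d) != number of rows (%d)",
          length(channel_labels), nrow(data))
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stopf("fs must be a positive scalar")
  if (!all(is.finite(data))) stopf("recording data must be finite")
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channels = channel_labels,
                 annotations = annotations),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples (%.1f s @ %g Hz)\n",
              nrow(x$data), ncol(x$data), ncol(x$data) / x$fs, x$fs))
  cat("  channels:", paste(utils::head(x$channels, 8), collapse = " "),
      if (length(x$channels) > 8) "..." else "", "\n")
  if (!is.null(x$annotations)) {
    cat(sprintf("  annotations: %d events\n", nrow(x$annotations)))
  }
  invisible(x)
}

n_samples <- function(recording) ncol(recording$data)

#' Epoched EEG container
#'
#' Trials x channels x time array time-locked to stimulus onsets, with the time
#' axis in seconds relative to onset and one metadata row per trial.
#'
#' @param data numeric 3-D array `[trial, channel, time]` in microvolts.
#' @param fs sampling rate in Hz.
#' @param times numeric vector of epoch times in seconds (length = `dim(data)[3]`).
#' @param channels character channel labels (length = `dim(data)[2]`).
#' @param metadata data.frame with one row per trial.
#' @return object of class `eeg_epochs`.
#' @export
new_epochs <- function(data, fs, times, channels, metadata) {
  stopifnot(length(dim(data)) == 3)
  if (dim(data)[3] != length(times)) stopf("times length mismatch")
  if (dim(data)[2] != length(channels)) stopf("channels length mismatch")
  if (dim(data)[1] != nrow(metadata)) stopf("metadata rows must equal trial count")
  structure(list(data = data, fs = fs, times = times, channels = channels,
                 metadata = metadata),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples [%0.3f, %0.3f] s\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$times), max(x$times)))
  invisible(x)
}

n_trials <- function(epochs) dim(epochs$data)[1]

# subset trials keeping structure (internal)
subset_epochs <- function(epochs, keep) {
  new_epochs(epochs$data[keep, , , drop = FALSE], epochs$fs, epochs$times,
             epochs$channels, epochs$metadata[keep, , drop = FALSE])
}
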