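# Preprocessing: zero-phase filtering, moving-window artifact detection,
# channel interpolation / segment exclusion, and epoching.

# RBJ biquad notch coefficients (internal)
notch_coefficients <- function(f0, fs, q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Band-pass and notch filter a recording
#'
#' Applies a zero-phase order-4 Butterworth band-pass (0.3-49 Hz for resting
#' data, 0.3-40 Hz for ERP data) followed by a zero-phase 60 Hz IIR notch
#' (Q = 30). Zero-phase (forward-backward) application preserves component
#' latencies.
#'
#' @param recording an `eeg_recording`.
#' @param mode `"resting"` or `"erp"` (selects the upper band edge).
#' @return filtered `eeg_recording` of identical shape.
#' @export
filter_recording <- function(recording, mode = c("resting", "erp")) {
  mode <- match.arg(mode)
  fs <- recording$fs
  if (n_samples(recording) < 2 * fs) stopf("recording too short to filter (< 2 s)")
  hi <- if (mode == "resting") 49 else 40
  bp <- signal::butter(2, c(0.3, hi) / (fs / 2), type = "pass")
  nc <- notch_coefficients(60, fs)
  data <- recording$data
  for (ch in seq_len(nrow(data))) {
    x <- signal::filtfilt(bp, data[ch, ])
    if (fs / 2 > 60) x <- signal::filtfilt(signal::Arma(b = nc$b, a = nc$a), x)
    data[ch, ] <- x
  }
  new_recording(data, fs, recording$channels, recording$annotations)
}

#' Scan a recording for artifact segments
#'
#' Slides a 2-s window with 50% overlap (1-s hop) over the recording and flags,
#' per window and channel: (i) window power on the channel greater than
#' `power_ratio` (8) times the mean window power across all channels, or
#' (ii) absolute amplitude above `amp_thresh` (400 uV) for more than half of
#' the window's samples, or within-window peak-to-peak range above
#' `p2p_thresh` (500 uV).
#'
#' @param recording an `eeg_recording` of at least 2 s.
#' @param power_ratio,amp_thresh,amp_frac,p2p_thresh detection thresholds.
#' @return object of class `segment_mask`: data.frame of windows with a list
#'   column of flagged channels and the triggering criteria.
#' @export
scan_artifacts <- function(recording, power_ratio = 8, amp_thresh = 400,
                           amp_frac = 0.5, p2p_thresh = 500) {
  fs <- recording$fs
  n <- n_samples(recording)
  win <- round(2 * fs)
  hop <- round(fs)
  if (n < win) stopf("recording shorter than one 2-s window")
  starts <- seq(1, n - win + 1, by = hop)
  data <- recording$data
  nch <- nrow(data)
  flagged <- vector("list", length(starts))
  criteria <- vector("list", length(starts))
  for (w in seq_along(starts)) {
    idx <- starts[w]:(starts[w] + win - 1)
    seg <- data[, idx, drop = FALSE]
    pw <- rowMeans(seg^2)
    c1 <- pw > power_ratio * mean(pw)
    over <- rowMeans(abs(seg) > amp_thresh) > amp_frac
    p2p <- apply(seg, 1, function(x) max(x) - min(x)) > p2p_thresh
    c2 <- over | p2p
    hit <- as.integer(which(c1 | c2))
    flagged[[w]] <- hit
    criteria[[w]] <- unname(ifelse(c1[hit] & c2[hit], "both",
                                   ifelse(c1[hit], "power", "amplitude")))
  }
  structure(list(window_start = starts, window_end = starts + win - 1,
                 flagged = flagged, criteria = criteria,
                 n_channels = nch, fs = fs, n_samples = n),
            class = "segment_mask")
}

#' @export
print.segment_mask <- function(x, ...) {
  nf <- sum(lengths(x$flagged) > 0)
  cat(sprintf("<segment_mask> %d windows (2 s, 1 s hop), %d flagged\n",
              length(x$window_start), nf))
  invisible(x)
}

# merge overlapping [start, end] intervals (internal)
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0) return(intervals)
  intervals <- intervals[order(intervals[, 1]), , drop = FALSE]
  out <- intervals[1, , drop = FALSE]
  for (i in seq_len(nrow(intervals))[-1]) {
    if (intervals[i, 1] <= out[nrow(out), 2] + 1) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], intervals[i, 2])
    } else {
      out <- rbind(out, intervals[i, , drop = FALSE])
    }
  }
  out
}

#' Repair single-channel artifacts, mark multi-channel segments for exclusion
#'
#' Windows with exactly one flagged channel have that channel's samples
#' replaced by the average of its nearest montage neighbours (computed from the
#' unflagged channels); windows with two or more flagged channels are added to
#' the exclusion intervals (merged when overlapping). A sample is excluded if
#' any covering window is excluded; interpolation is applied on the union of
#' single-channel flagged windows. Samples outside flagged windows are never
#' altered.
#'
#' @param recording an `eeg_recording`.
#' @param mask a `segment_mask` from [scan_artifacts()].
#' @param montage montage data.frame (defaults to the standard montage matched
#'   by channel label).
#' @param n_neighbors number of neighbours averaged in the interpolation.
#' @return list with `recording` (repaired), `exclusion_intervals` (two-column
#'   matrix of sample ranges) and `status` (per-window: clean / interpolated /
#'   excluded).
#' @export
repair_or_reject <- function(recording, mask, montage = NULL, n_neighbors = 4) {
  stopifnot(inherits(mask, "segment_mask"))
  if (mask$n_channels != nrow(recording$data) ||
      mask$n_samples != n_samples(recording)) {
    stopf("mask does not match recording dimensions")
  }
  nch <- nrow(recording$data)
  if (is.null(montage)) {
    full <- default_montage(20)
    montage <- full[match(recording$channels, full$label), ]
    if (anyNA(montage$x)) {
      montage <- data.frame(label = recording$channels,
                            x = seq_len(nch), y = 0)
    }
  }
  data <- recording$data
  status <- rep("clean", length(mask$window_start))
  excl <- matrix(numeric(0), ncol = 2)
  # per-channel union of samples to interpolate
  interp_samples <- vector("list", nch)
  for (w in seq_along(mask$window_start)) {
    hit <- mask$flagged[[w]]
    if (length(hit) == 0) next
    rng <- mask$window_start[w]:mask$window_end[w]
    if (length(hit) == 1 && nch > 1) {
      status[w] <- "interpolated"
      interp_samples[[hit]] <- c(interp_samples[[hit]], rng)
    } else {
      status[w] <- "excluded"
      excl <- rbind(excl, c(mask$window_start[w], mask$window_end[w]))
    }
  }
  for (ch in seq_len(nch)) {
    smp <- unique(interp_samples[[ch]])
    if (length(smp) == 0) next
    d <- sqrt((montage$x - montage$x[ch])^2 + (montage$y - montage$y[ch])^2)
    d[ch] <- Inf
    nb <- order(d)[seq_len(min(n_neighbors, nch - 1))]
    data[ch, smp] <- colMeans(data[nb, smp, drop = FALSE])
  }
  excl <- merge_intervals(excl)
  list(recording = new_recording(data, recording$fs, recording$channels,
                                 recording$annotations),
       exclusion_intervals = excl, status = status)
}

#' Epoch a recording around stimulus events
#'
#' Cuts one epoch per event over `window` seconds relative to stimulus onset
#' (default -0.8 to +1.3 s). Events whose epoch would underrun or overrun the
#' recording, or intersect an exclusion interval, are dropped. Event metadata
#' is carried over to the epochs.
#'
#' @param recording an `eeg_recording`.
#' @param events data.frame with a `sample` column (onset sample index) or an
#'   `onset_s` column; remaining columns are copied as metadata.
#' @param window epoch window in seconds relative to onset.
#' @param exclusion_intervals optional two-column matrix of excluded sample ranges.
#' @return an `eeg_epochs`; zero surviving events yield an empty epoch set
#'   (with a warning).
#' @export
epoch_recording <- function(recording, events, window = c(-0.8, 1.3),
                            exclusion_intervals = NULL) {
  fs <- recording$fs
  if (!("sample" %in% names(events))) {
    if (!("onset_s" %in% names(events))) stopf("events need 'sample' or 'onset_s'")
    events$sample <- round(events$onset_s * fs) + 1L
  }
  n <- n_samples(recording)
  if (any(events$sample < 1 | events$sample > n)) stopf("events outside recording bounds")
  n_pre <- round(-window[1] * fs)
  n_post <- round(window[2] * fs)
  len <- n_pre + n_post
  times <- (seq_len(len) - 1 - n_pre) / fs
  keep <- logical(nrow(events))
  for (i in seq_len(nrow(events))) {
    lo <- events$sample[i] - n_pre
    hi <- events$sample[i] + n_post - 1
    ok <- lo >= 1 && hi <= n
    if (ok && !is.null(exclusion_intervals) && nrow(exclusion_intervals) > 0) {
      ok <- !any(exclusion_intervals[, 1] <= hi & exclusion_intervals[, 2] >= lo)
    }
    keep[i] <- ok
  }
  kept <- which(keep)
  if (length(kept) == 0) {
    warning("no epochs survived epoching", call. = FALSE)
  }
  arr <- array(0, c(length(kept), nrow(recording$data), len))
  for (j in seq_along(kept)) {
    i <- kept[j]
    arr[j, , ] <- recording$data[, (events$sample[i] - n_pre):(events$sample[i] + n_post - 1)]
  }
  new_epochs(arr, fs, times, recording$channels,
             events[kept, , drop = FALSE])
}

#' Summarize preprocessing data quality
#'
#' Percent usable data and flag counts, mirroring the quality metrics a
#' preprocessing report should carry.
#'
#' @param mask a `segment_mask`.
#' @param repair result of [repair_or_reject()].
#' @return list with `percent_usable`, `n_windows`, `n_interpolated`,
#'   `n_excluded`, `flags_by_criterion`.
#' @export
preprocessing_report <- function(mask, repair) {
  excl <- repair$exclusion_intervals
  n_excl_samples <- if (nrow(excl)) sum(excl[, 2] - excl[, 1] + 1) else 0
  crit <- unlist(mask$criteria)
  list(
    percent_usable = 100 * (1 - n_excl_samples / mask$n_samples),
    n_windows = length(mask$window_start),
    n_interpolated = sum(repair$status == "interpolated"),
    n_excluded = sum(repair$status == "excluded"),
    flags_by_criterion = c(power = sum(crit == "power"),
                           amplitude = sum(crit == "amplitude"),
                           both = sum(crit == "both"))
  )
}
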