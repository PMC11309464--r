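# ERP analysis: baseline correction, trial rejection, averaging with the
# minimum-trial rule, classical component measurement, grand averages and
# behavioural summaries.

#' Default ERP component analysis windows
#'
#' Windows (seconds post-onset) centered on the classical components: the
#' early positive peak of the vigilance task (P1), the early recognition
#' component (P200), and the late positive potential (LPP). Exposed as a
#' function so analyses can override them while keeping defaults reproducible.
#'
#' @return named list of two-element numeric vectors.
#' @export
component_windows <- function() {
  list(P1 = c(0.08, 0.20), P200 = c(0.13, 0.28), LPP = c(0.40, 0.80))
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean amplitude over the 100 ms window
#' before stimulus onset (`[-0.1, 0)` s). Idempotent.
#'
#' @param epochs an `eeg_epochs` whose time axis covers `[-0.1, 0)`.
#' @return baseline-corrected `eeg_epochs`.
#' @export
baseline_correct <- function(epochs) {
  idx <- which(epochs$times >= -0.1 & epochs$times < 0)
  if (length(idx) == 0) stopf("epoch window does not cover the baseline [-0.1, 0) s")
  base <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
  data <- sweep(epochs$data, c(1, 2), base, "-")
  new_epochs(data, epochs$fs, epochs$times, epochs$channels, epochs$metadata)
}

#' Reject artifact-contaminated and incorrect trials
#'
#' Drops trials whose absolute amplitude exceeds `amp_thresh` (100 uV) on any
#' channel within `[-0.05, 0.7]` s relative to onset, and trials without a
#' correct response (incorrect or missing). The two criteria are independent,
#' so their application order does not matter.
#'
#' @param epochs baseline-corrected `eeg_epochs` with a `correct` metadata column.
#' @param amp_thresh amplitude threshold in microvolts.
#' @param window amplitude-scan window in seconds.
#' @param require_correct drop incorrect/missing-response trials.
#' @return surviving `eeg_epochs`, with attribute `rejection_counts`.
#' @export
reject_trials <- function(epochs, amp_thresh = 100, window = c(-0.05, 0.7),
                          require_correct = TRUE) {
  idx <- which(epochs$times >= window[1] & epochs$times <= window[2])
  nt <- n_trials(epochs)
  over <- vapply(seq_len(nt), function(i) {
    max(abs(epochs$data[i, , idx])) > amp_thresh
  }, logical(1))
  bad_resp <- if (require_correct) {
    corr <- epochs$metadata$correct
    is.na(corr) | !corr
  } else rep(FALSE, nt)
  keep <- !(over | bad_resp)
  out <- subset_epochs(epochs, keep)
  attr(out, "rejection_counts") <- c(amplitude = sum(over),
                                     response = sum(bad_resp),
                                     kept = sum(keep))
  out
}

#' Average surviving trials into a subject ERP
#'
#' Pointwise mean across trials of the given stimulus type. Acquisitions with
#' fewer than `min_trials` (9) surviving trials are excluded: a condition of
#' class `eegmci_too_few_trials` is raised rather than returning a silently
#' unstable average.
#'
#' @param epochs an `eeg_epochs`.
#' @param stimulus_type trial type to average (`NULL` = all trials).
#' @param min_trials minimum number of trials for a valid average.
#' @return object of class `erp_average`: `waveform` (channels x time),
#'   `times`, `n_trials`, `stimulus_type`, `channels`.
#' @export
average_erp <- function(epochs, stimulus_type = NULL, min_trials = 9) {
  keep <- if (is.null(stimulus_type)) rep(TRUE, n_trials(epochs)) else
    epochs$metadata$trial_type == stimulus_type
  nt <- sum(keep)
  if (nt < min_trials) {
    stop(errorCondition(
      sprintf("only %d trials remain for averaging (minimum %d): acquisition excluded",
              nt, min_trials),
      class = c("eegmci_too_few_trials", "error"),
      n_trials = nt))
  }
  wf <- apply(epochs$data[keep, , , drop = FALSE], c(2, 3), mean)
  rownames(wf) <- epochs$channels
  structure(list(waveform = wf, times = epochs$times, n_trials = nt,
                 stimulus_type = stimulus_type %||% "all",
                 channels = epochs$channels),
            class = "erp_average")
}

#' @export
print.erp_average <- function(x, ...) {
  cat(sprintf("<erp_average> %s: %d channels, %d trials, [%0.3f, %0.3f] s\n",
              x$stimulus_type, nrow(x$waveform), x$n_trials,
              min(x$times), max(x$times)))
  invisible(x)
}

#' Measure a classical ERP component
#'
#' Per channel, within the component's analysis window: mean amplitude, peak
#' (maximum) amplitude, and peak latency (time of the first maximum; ties are
#' broken toward the earlier sample).
#'
#' @param erp an `erp_average`.
#' @param component `"P1"`, `"P200"` or `"LPP"`.
#' @param window optional custom window in seconds (overrides
#'   [component_windows()]).
#' @return data.frame with `channel`, `mean_uv`, `peak_uv`, `latency_s`, and
#'   attributes `component`, `window`.
#' @export
measure_component <- function(erp, component = c("P1", "P200", "LPP"),
                              window = NULL) {
  component <- match.arg(component)
  win <- window %||% component_windows()[[component]]
  idx <- which(erp$times >= win[1] & erp$times <= win[2])
  if (length(idx) == 0) stopf("analysis window outside the epoch")
  seg <- erp$waveform[, idx, drop = FALSE]
  peaks <- apply(seg, 1, max)
  lat <- erp$times[idx[apply(seg, 1, which.max)]]
  out <- data.frame(channel = erp$channels, mean_uv = rowMeans(seg),
                    peak_uv = peaks, latency_s = lat,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "component") <- component
  attr(out, "window") <- win
  out
}

#' Grand average across subjects
#'
#' Unweighted mean of per-subject average waveforms (every subject counts
#' equally regardless of how many trials entered their average).
#'
#' @param erp_list list of `erp_average` objects on a common time axis.
#' @return an `erp_average`; `n_trials` holds the number of subjects.
#' @export
grand_average <- function(erp_list) {
  stopifnot(length(erp_list) >= 1)
  t0 <- erp_list[[1]]$times
  for (e in erp_list) {
    if (length(e$times) != length(t0) || max(abs(e$times - t0)) > 1e-9) {
      stopf("time axes differ across subjects")
    }
  }
  wf <- Reduce(`+`, lapply(erp_list, `[[`, "waveform")) / length(erp_list)
  structure(list(waveform = wf, times = t0, n_trials = length(erp_list),
                 stimulus_type = erp_list[[1]]$stimulus_type,
                 channels = erp_list[[1]]$channels),
            class = "erp_average")
}

#' Crop an ERP average to the analysis time grid
#'
#' Restricts the waveform to `n_points` samples starting at the first time
#' at or after `from` -- by default the 256-point `[-0.2, 0.8)` s grid used by
#' the channel x time cluster analysis.
#'
#' @param erp an `erp_average`.
#' @param from start time in seconds.
#' @param n_points number of samples to keep.
#' @return cropped `erp_average`.
#' @export
crop_erp <- function(erp, from = -0.2, n_points = 256) {
  i0 <- which(erp$times >= from - 1e-9)[1]
  if (is.na(i0) || i0 + n_points - 1 > length(erp$times)) {
    stopf("epoch does not cover the requested grid")
  }
  idx <- i0:(i0 + n_points - 1)
  structure(list(waveform = erp$waveform[, idx, drop = FALSE],
                 times = erp$times[idx], n_trials = erp$n_trials,
                 stimulus_type = erp$stimulus_type, channels = erp$channels),
            class = "erp_average")
}

#' Behavioural summary of a task session
#'
#' Accuracy as the percentage of scoreable trials answered correctly
#' (non-responses count as incorrect) and mean reaction time over correct
#' trials only.
#'
#' @param events trial table with `phase`, `trial_type`, `correct`, `rt_s`.
#' @param classes stimulus classes to score (`NULL` = all test-phase trials).
#' @return list with `accuracy_pct`, `mean_rt_s` (NA if no correct trials),
#'   `n_trials`, `n_correct`.
#' @export
behavioral_summary <- function(events, classes = NULL) {
  sc <- events$phase == "test"
  if (!is.null(classes)) sc <- sc & events$trial_type %in% classes
  ev <- events[sc, , drop = FALSE]
  if (nrow(ev) == 0) stopf("no scoreable trials")
  correct <- !is.na(ev$correct) & ev$correct
  acc <- 100 * sum(correct) / nrow(ev)
  rts <- ev$rt_s[correct & !is.na(ev$rt_s)]
  list(accuracy_pct = acc,
       mean_rt_s = if (length(rts)) mean(rts) else NA_real_,
       n_trials = nrow(ev), n_correct = sum(correct))
}
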