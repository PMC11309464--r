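# Resting-state power spectral density: Kaiser-windowed 1-s epochs with 50%
# overlap, unscaled psd(f) = (1/Fs) * 2 * |X(f)|^2 at 1-Hz bins 1-40, linear
# smoothing over the 3 overlapping epochs centered on each non-overlapping
# epoch, log10, and averaging over the session.

#' Canonical frequency band definitions
#'
#' Band edges in Hz, bins inclusive on both ends. Neighbouring bands share
#' edge bins (3 Hz, 13 Hz) and Beta/Gamma overlap (25-30 Hz); the printed
#' historical definitions are reproduced verbatim rather than disjointed.
#'
#' @return data.frame with `name`, `lo`, `hi`.
#' @export
default_bands <- function() {
  data.frame(
    name = c("Delta", "SlowTheta", "Theta", "SlowAlpha", "Alpha",
             "SlowBeta", "Beta", "Gamma"),
    lo = c(1, 3, 3, 8, 8, 13, 13, 25),
    hi = c(3, 5, 7, 10, 13, 20, 30, 40),
    stringsAsFactors = FALSE
  )
}

#' Compute the resting-state PSD matrix
#'
#' Pipeline per channel: (1) segment into 1-s epochs with 50% overlap;
#' (2) per epoch, apply a Kaiser window (beta = 6), FFT of length `fs`, and
#' form the unscaled density `psd(f) = (1/Fs) * 2 * |X(f)|^2` at the 1-Hz bins
#' 1-40; (3) for the relative dialect, divide each bin by the bin sum over
#' 1-40 Hz per channel and epoch; (4) average the linear psd over the three
#' overlapping epochs centered on each non-overlapping (odd) epoch, using the
#' available neighbours at the session edges; (5) log10 (values floored at
#' 1e-12); (6) average the log values over the non-overlapping epochs of the
#' session, skipping epochs that intersect excluded intervals.
#'
#' @param recording a cleaned `eeg_recording` of at least 3 s.
#' @param dialect `"absolute"` or `"relative"`.
#' @param exclusion_intervals optional two-column matrix of excluded sample
#'   ranges; epochs intersecting them are skipped.
#' @return object of class `psd_matrix`: channels x 40 matrix of log10 PSD
#'   plus `dialect` and `n_epochs_used`.
#' @export
compute_psd <- function(recording, dialect = c("absolute", "relative"),
                        exclusion_intervals = NULL) {
  dialect <- match.arg(dialect)
  fs <- recording$fs
  if (fs != round(fs)) stopf("compute_psd requires an integer sampling rate")
  L <- as.integer(fs)
  hop <- L %/% 2L
  n <- n_samples(recording)
  if (n < 3 * L) stopf("recording shorter than 3 s")
  starts <- seq(1L, n - L + 1L, by = hop)
  K <- length(starts)
  w <- signal::kaiser(L, 6)
  nch <- nrow(recording$data)
  bins <- 1:40

  # linear psd per epoch: nch x 40 x K
  psd <- array(NA_real_, c(nch, 40, K))
  for (ch in seq_len(nch)) {
    segs <- matrix(0, L, K)
    for (k in seq_len(K)) {
      segs[, k] <- recording$data[ch, starts[k]:(starts[k] + L - 1)]
    }
    X <- stats::mvfft(segs * w)
    p <- (1 / fs) * 2 * Mod(X[bins + 1L, , drop = FALSE])^2
    if (dialect == "relative") {
      p <- sweep(p, 2, colSums(p), "/")
    }
    psd[ch, , ] <- p
  }

  excluded_epoch <- rep(FALSE, K)
  if (!is.null(exclusion_intervals) && nrow(exclusion_intervals) > 0) {
    for (k in seq_len(K)) {
      lo <- starts[k]; hi <- starts[k] + L - 1L
      excluded_epoch[k] <- any(exclusion_intervals[, 1] <= hi &
                                 exclusion_intervals[, 2] >= lo)
    }
  }

  centers <- seq(1L, K, by = 2L)  # non-overlapping epochs
  vals <- matrix(0, nch, 40)
  used <- 0L
  for (k in centers) {
    if (excluded_epoch[k]) next
    nb <- c(k - 1L, k, k + 1L)
    nb <- nb[nb >= 1L & nb <= K]
    nb <- nb[!excluded_epoch[nb]]
    sm <- apply(psd[, , nb, drop = FALSE], c(1, 2), mean)
    vals <- vals + log10(pmax(sm, 1e-12))
    used <- used + 1L
  }
  if (used < 3) stopf("fewer than 3 usable epochs")
  vals <- vals / used
  rownames(vals) <- recording$channels
  colnames(vals) <- as.character(bins)
  structure(list(values = vals, dialect = dialect, n_epochs_used = used,
                 channels = recording$channels, freqs = bins),
            class = "psd_matrix")
}

#' @export
print.psd_matrix <- function(x, ...) {
  cat(sprintf("<psd_matrix> %s dialect, %d channels x %d bins (%d epochs)\n",
              x$dialect, nrow(x$values), ncol(x$values), x$n_epochs_used))
  invisible(x)
}

#' Average log PSD within frequency bands
#'
#' Arithmetic mean of the log10 PSD bins inside each band, bins inclusive on
#' both band edges.
#'
#' @param psd a `psd_matrix`.
#' @param bands band definition data.frame (default [default_bands()]).
#' @return channels x bands numeric matrix.
#' @export
band_power <- function(psd, bands = default_bands()) {
  if (any(bands$lo < 1 | bands$hi > 40 | bands$lo > bands$hi)) {
    stopf("bands must satisfy 1 <= lo <= hi <= 40")
  }
  out <- vapply(seq_len(nrow(bands)), function(i) {
    rowMeans(psd$values[, as.character(bands$lo[i]:bands$hi[i]), drop = FALSE])
  }, numeric(nrow(psd$values)))
  out <- matrix(out, nrow = nrow(psd$values),
                dimnames = list(psd$channels, bands$name))
  out
}

#' Theta-to-alpha ratio
#'
#' Per-channel TAR computed as the difference of mean log10 band powers,
#' `meanlog(Theta) - meanlog(Alpha)` (the log of the power ratio). Elevated in
#' cognitive slowing.
#'
#' @param bp channels x bands matrix from [band_power()] containing `Theta`
#'   and `Alpha` columns.
#' @return named numeric vector, one TAR per channel.
#' @export
theta_alpha_ratio <- function(bp) {
  if (!all(c("Theta", "Alpha") %in% colnames(bp))) {
    stopf("band table must contain Theta and Alpha")
  }
  bp[, "Theta"] - bp[, "Alpha"]
}
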