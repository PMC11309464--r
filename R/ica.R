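# ICA-based artifact decontamination with a pluggable component classifier.
#
# The unmixing follows the standard independent-component contract used for
# EEG cleaning: full-rank PCA whitening (no dimension reduction) followed by a
# symmetric fixed-point iteration with a tanh contrast. Components are scored
# by an injectable classifier returning a brain probability in [0, 1]; any
# component below the rejection threshold (default 10%) is removed before
# remixing.

#' Fit a full-rank ICA decomposition (extended infomax)
#'
#' Extended-infomax ICA: full-rank PCA whitening (no dimension reduction)
#' followed by natural-gradient ascent of the infomax objective with a
#' per-component sub/super-Gaussian switch and learning-rate annealing, the
#' scheme standard EEG toolboxes use for artifact decomposition. Iteration
#' stops when the relative weight change falls below `tol` (or at `maxit`).
#' Deterministic given `seed` (which only perturbs the identity start). For
#' long recordings the unmixing matrix is estimated on an evenly strided
#' subsample of time points and then applied to all samples.
#'
#' @param x channels x samples numeric matrix.
#' @param seed integer seed.
#' @param maxit maximum gradient steps.
#' @param tol stopping threshold on the relative weight change.
#' @param max_fit_samples maximum number of time points used for estimation.
#' @return list with `sources` (components x samples), `mixing` (channels x
#'   components), `unmixing`, `center`, `converged`.
#' @export
fit_ica <- function(x, seed = 1L, maxit = 512, tol = 1e-6,
                    max_fit_samples = 20000L) {
  nch <- nrow(x)
  center <- rowMeans(x)
  xc <- x - center
  cv <- xc %*% t(xc) / ncol(xc)
  e <- eigen(cv, symmetric = TRUE)
  vals <- pmax(e$values, 1e-12)
  K <- diag(1 / sqrt(vals), nch) %*% t(e$vectors)
  z <- K %*% xc
  zfit <- if (ncol(z) > max_fit_samples) {
    z[, round(seq(1, ncol(z), length.out = max_fit_samples)), drop = FALSE]
  } else z
  nfit <- ncol(zfit)

  W <- diag(nch) + with_seed(derive_seed(seed, "ica"),
                             matrix(stats::rnorm(nch * nch, 0, 1e-3), nch, nch))
  lr <- 0.01
  id <- diag(nch)
  signs <- rep(1, nch)
  old_delta <- NULL
  converged <- FALSE
  for (it in seq_len(maxit)) {
    u <- W %*% zfit
    if (it %% 10 == 1) {
      # sub/super-Gaussian switch from the sign of the excess kurtosis
      kur <- rowMeans(u^4) / rowMeans(u^2)^2 - 3
      signs <- ifelse(kur >= 0, 1, -1)
    }
    y <- tanh(u)
    grad <- id - (signs * y) %*% t(u) / nfit - u %*% t(u) / nfit
    dW <- lr * grad %*% W
    if (!all(is.finite(dW))) {
      lr <- lr / 2
      if (lr < 1e-8) break
      next
    }
    W <- W + dW
    delta <- as.vector(dW)
    change <- sum(delta^2) / sum(W^2)
    if (!is.null(old_delta)) {
      angle <- sum(delta * old_delta) /
        sqrt(sum(delta^2) * sum(old_delta^2) + 1e-30)
      if (angle < 0.5) lr <- lr * 0.95  # anneal when the step turns > 60 deg
    }
    old_delta <- delta
    if (change < tol) { converged <- TRUE; break }
  }
  if (!all(is.finite(W))) {
    return(list(sources = z, mixing = e$vectors %*% diag(sqrt(vals), nch),
                unmixing = K, center = center, converged = FALSE))
  }
  unmixing <- W %*% K
  mixing <- e$vectors %*% diag(sqrt(vals), nch) %*% solve(W)
  sources <- unmixing %*% xc
  list(sources = sources, mixing = mixing, unmixing = unmixing,
       center = center, converged = converged)
}

#' Heuristic component classifier
#'
#' Scores each independent component with a pseudo-probability of being brain
#' activity from three markers of typical EEG artifacts: excess kurtosis
#' (transients), low-frequency power fraction (drifts and movement) and
#' concentration of the mixing column on a single channel (electrode
#' artifacts). This is a deliberately simple stand-in for pre-trained
#' component classifiers; any function with the same signature can be
#' injected into [decontaminate()].
#'
#' @param ica result of [fit_ica()].
#' @param fs sampling rate in Hz.
#' @return numeric vector of brain probabilities in `[0, 1]`.
#' @export
heuristic_component_classifier <- function(ica, fs) {
  s <- ica$sources
  nc <- nrow(s)
  probs <- numeric(nc)
  for (i in seq_len(nc)) {
    x <- s[i, ]
    x <- x / stats::sd(x)
    kurt <- mean(x^4) - 3
    spec <- Mod(stats::fft(x))^2
    f <- (seq_along(spec) - 1) * fs / length(spec)
    f <- pmin(f, fs - f)
    lowfrac <- sum(spec[f < 2 & f > 0]) / sum(spec[f > 0])
    load <- abs(ica$mixing[, i])
    conc <- max(load) / sqrt(sum(load^2))
    score <- 2 - 0.25 * max(kurt - 3, 0) - 4 * max(lowfrac - 0.6, 0) -
      8 * max(conc - 0.85, 0)
    probs[i] <- stats::plogis(score)
  }
  probs
}

#' Remove non-brain independent components
#'
#' Unmixes the data with a full-rank ICA, applies the injected component
#' classifier, rejects every component whose brain probability is below
#' `threshold` (default 10%), and remixes the remaining components. Works on
#' continuous recordings (resting data) and on epoched data (ERP tasks; the
#' decomposition is fitted on the concatenated epochs).
#'
#' @param x an `eeg_recording` or `eeg_epochs`.
#' @param classifier function `(ica, fs) -> brain probabilities`; defaults to
#'   [heuristic_component_classifier()].
#' @param threshold rejection threshold on the brain probability.
#' @param seed integer seed passed to [fit_ica()].
#' @param ... further arguments to [fit_ica()].
#' @return object of the same class as `x`, with attributes
#'   `n_components_rejected` and `ica_converged`. If the ICA does not
#'   converge, the input is returned unchanged with a warning and
#'   `ica_converged = FALSE`.
#' @export
decontaminate <- function(x, classifier = heuristic_component_classifier,
                          threshold = 0.10, seed = 1L, ...) {
  if (inherits(x, "eeg_recording")) {
    mat <- x$data
  } else if (inherits(x, "eeg_epochs")) {
    d <- x$data
    nt <- dim(d)[1]; nch <- dim(d)[2]; ns <- dim(d)[3]
    mat <- matrix(aperm(d, c(2, 3, 1)), nch, ns * nt)
  } else stopf("x must be an eeg_recording or eeg_epochs")
  fs <- x$fs
  ica <- fit_ica(mat, seed = seed, ...)
  if (!ica$converged) {
    warning("ICA did not converge; returning data unchanged", call. = FALSE)
    attr(x, "ica_converged") <- FALSE
    attr(x, "n_components_rejected") <- 0L
    return(x)
  }
  probs <- classifier(ica, fs)
  keep <- which(probs >= threshold)
  clean <- if (length(keep) == 0) {
    matrix(0, nrow(mat), ncol(mat))
  } else {
    ica$mixing[, keep, drop = FALSE] %*% ica$sources[keep, , drop = FALSE] +
      ica$center
  }
  out <- if (inherits(x, "eeg_recording")) {
    new_recording(clean, fs, x$channels, x$annotations)
  } else {
    d <- aperm(array(clean, c(dim(x$data)[2], dim(x$data)[3], dim(x$data)[1])),
               c(3, 1, 2))
    new_epochs(d, fs, x$times, x$channels, x$metadata)
  }
  attr(out, "ica_converged") <- TRUE
  attr(out, "n_components_rejected") <- length(probs) - length(keep)
  out
}
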