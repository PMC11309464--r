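# Signal-level synthetic EEG: 1/f background plus Gaussian-envelope band
# oscillators for resting data, and template ERPs (Gaussian early peak,
# half-cosine LPP plateau) added to ongoing activity for task data. Group
# effects enter through multiplicative amplitude/latency shifts proportional
# to the subject's latent severity and the configured effect sizes.

# Designed between-subject SD of log10 band power (the unit in which the
# spectral effect sizes are expressed). The subject amplitude variability
# below is chosen so that the realized SD of measured log10 band power matches
# this constant; the match is verified by the generator-calibration tests.
SIGMA_BANDPOWER_LOG10 <- 0.2
AMP_TRAIT_SD_LOG10 <- 0.12   # per-subject log10 SD of oscillator amplitude
BG_TRAIT_SD_LOG10 <- 0.05    # per-subject log10 SD of background amplitude
# Fraction of an injected oscillator log-power shift that the band log-power
# measure expresses (edge bins of a band are partly background-dominated, so a
# shift of the oscillator moves the measured band mean by less than itself).
# Derived from the generator's own spectral design; the injected shift is
# divided by these so that configured effect sizes are recovered 1:1.
THETA_BAND_EXPRESSION <- 0.80
BETA_BAND_EXPRESSION <- 0.95

# spectrally shaped Gaussian noise, unit RMS; computed at a padded FFT-friendly
# length and truncated (internal)
shaped_noise <- function(n, fs, shape_fn) {
  np <- stats::nextn(n, c(2, 3, 5))
  w <- stats::rnorm(np)
  f <- (seq_len(np) - 1) * fs / np
  f <- pmin(f, fs - f)
  x <- Re(stats::fft(stats::fft(w) * shape_fn(f), inverse = TRUE))[seq_len(n)] / np
  x / stats::sd(x)
}

# 1/f^chi background noise, unit RMS (internal)
sim_colored_noise <- function(n, fs, exponent = 1) {
  shaped_noise(n, fs, function(f) ifelse(f < 0.25, 0, f^(-exponent / 2)))
}

# band-limited oscillatory noise with a Gaussian spectral envelope, unit RMS
sim_band_noise <- function(n, fs, f0, sigma) {
  shaped_noise(n, fs, function(f) exp(-(f - f0)^2 / (2 * sigma^2)))
}

# slow lognormal amplitude envelope (waxing/waning bursts, ~1-2 s timescale);
# makes sources non-Gaussian, as cortical rhythms are, and hence separable by
# ICA (internal)
sim_burst_envelope <- function(n, fs, strength = 0.4) {
  slow <- shaped_noise(n, fs, function(f) exp(-f^2 / (2 * 0.5^2)))
  env <- exp(strength * slow)
  env / sqrt(mean(env^2))
}

# shared ongoing-EEG generator: background + theta/alpha/beta oscillators.
# mults: named multipliers (theta, alpha, beta, bg) already including trait
# and disease shifts. Returns channels x n matrix in microvolts.
sim_ongoing_eeg <- function(n, fs, montage, mults) {
  nch <- nrow(montage)
  data <- matrix(0, nch, n)
  for (ch in seq_len(nch)) {
    data[ch, ] <- 7 * mults[["bg"]] * sim_colored_noise(n, fs, 1) *
      sim_burst_envelope(n, fs, 0.25)
  }
  osc <- list(
    theta = list(f0 = 5, sigma = 1.8, rms = 13,
                 topo = montage_topography(montage, 0, 0.55, 0.8, 0.55)),
    alpha = list(f0 = 10, sigma = 1.0, rms = 14,
                 topo = montage_topography(montage, 0, -1.0, 0.8, 0.25)),
    beta = list(f0 = 16.5, sigma = 2.3, rms = 8,
                topo = montage_topography(montage, 0, 0, 0.8, 0.55))
  )
  for (nm in names(osc)) {
    o <- osc[[nm]]
    src <- sim_band_noise(n, fs, o$f0, o$sigma) * sim_burst_envelope(n, fs, 0.4)
    data <- data + (o$rms * mults[[nm]] * o$topo) %o% src
  }
  data
}

#' Simulate a resting-state eyes-closed EEG recording
#'
#' Five minutes (configurable) of multichannel EEG modelled as 1/f background
#' noise plus coherent band-limited oscillators (alpha strongest occipitally,
#' theta fronto-midline, beta central). For MCI subjects the theta oscillator
#' power is elevated and the beta oscillator power suppressed in proportion to
#' the subject's latent severity and the configured effect sizes, expressed as
#' Hedges' g on log10 band power.
#'
#' @param subject one row of a [make_cohort()] table (data.frame or list).
#' @param visit visit index (1 or 2).
#' @param config the [cohort_config()].
#' @return an `eeg_recording` in microvolts.
#' @export
simulate_resting <- function(subject, visit = 1, config) {
  stopifnot(inherits(config, "cohort_config"))
  z <- subject_traits(subject, visit, config)
  sev <- if (subject$group == "MCI") subject$severity else 0
  mults <- list(
    theta = 10^(AMP_TRAIT_SD_LOG10 * z[1] +
                  config$theta_shift * SIGMA_BANDPOWER_LOG10 * sev /
                    (2 * THETA_BAND_EXPRESSION)),
    alpha = 10^(AMP_TRAIT_SD_LOG10 * z[2]),
    beta = 10^(AMP_TRAIT_SD_LOG10 * z[3] +
                 config$beta_shift * SIGMA_BANDPOWER_LOG10 * sev /
                   (2 * BETA_BAND_EXPRESSION)),
    bg = 10^(BG_TRAIT_SD_LOG10 * z[4])
  )
  vseed <- if (visit == 1) subject$visit_seed1 else subject$visit_seed2
  n <- round(config$resting_duration_s * config$fs)
  data <- with_seed(derive_seed(vseed, "resting"),
                    sim_ongoing_eeg(n, config$fs, config$montage, mults))
  new_recording(data, config$fs, config$montage$label)
}

# per-task behavioural parameters (internal)
behavior_params <- function(task) {
  switch(task,
    cvt = list(base_acc = 0.95, acc_sd_pp = 12, base_rt = 0.45, rt_sd_s = 0.043),
    sir = list(base_acc = 0.85, acc_sd_pp = 18, base_rt = 0.75, rt_sd_s = 0.205),
    stopf("unknown task '%s'", task))
}

#' Simulate behavioural responses for a task session
#'
#' Draws per-trial response correctness (Bernoulli with a subject-level
#' accuracy that is reduced in MCI) and reaction times (a subject-level offset
#' plus a log-normal per-trial component; the offset is slowed in MCI by the
#' configured shift times severity). Encoding-phase trials are not scored.
#'
#' @param subject cohort row; @param design a `task_design`;
#' @param config the [cohort_config()]; @param visit visit index.
#' @return the design's trial table with `correct` (logical, NA for encoding)
#'   and `rt_s` columns appended.
#' @export
simulate_behavior <- function(subject, design, config, visit = 1) {
  z <- subject_traits(subject, visit, config)
  sev <- if (subject$group == "MCI") subject$severity else 0
  p <- behavior_params(design$task)
  acc <- min(0.998, max(0.05,
    p$base_acc - config$accuracy_shift[[design$task]] / 100 * sev +
      p$acc_sd_pp / 100 * z[9]))
  rt0 <- p$base_rt + p$rt_sd_s * z[8] +
    config$rt_shift_ms[[design$task]] / 1000 * sev
  rt0 <- max(rt0, 0.15)
  vseed <- if (visit == 1) subject$visit_seed1 else subject$visit_seed2
  trials <- design$trials
  with_seed(derive_seed(vseed, "behavior", design$task), {
    n <- nrow(trials)
    scoreable <- trials$phase == "test"
    p_miss <- min(0.3, 0.01 + 0.02 * max(sev, 0))
    responded <- stats::runif(n) > p_miss
    correct <- responded & (stats::runif(n) < acc)
    rt <- rt0 + stats::rlnorm(n, log(0.08), 0.5)
    trials$correct <- ifelse(scoreable, correct, NA)
    trials$rt_s <- ifelse(scoreable & responded, rt, NA_real_)
  })
  trials
}

#' Simulate a full ERP task session
#'
#' Generates continuous EEG for a task schedule: ongoing background activity
#' (as in [simulate_resting()]) on which each trial superimposes an
#' event-related template with two components, an early positive peak
#' (Gaussian; fronto-central topography; ~120 ms in the vigilance task, ~200 ms
#' in the recognition task) and a late positive potential (half-cosine plateau
#' over 400-800 ms; centro-parietal topography). MCI subjects have the early
#' peak delayed by `early_latency_shift_ms * severity` and the LPP amplitude
#' scaled down according to `lpp_amplitude_shift`. Behavioural responses come
#' from [simulate_behavior()].
#'
#' @inheritParams simulate_behavior
#' @return list with elements `recording` (an `eeg_recording`) and `events`
#'   (trial table with `sample`, `correct`, `rt_s`).
#' @export
simulate_erp_session <- function(subject, design, config, visit = 1) {
  stopifnot(inherits(config, "cohort_config"), inherits(design, "task_design"))
  fs <- config$fs
  montage <- config$montage
  z <- subject_traits(subject, visit, config)
  sev <- if (subject$group == "MCI") subject$severity else 0
  dur <- max(design$trials$onset_s) + 2.5
  n <- round(dur * fs)

  mults <- list(theta = 10^(AMP_TRAIT_SD_LOG10 * z[1]),
                alpha = 0.6 * 10^(AMP_TRAIT_SD_LOG10 * z[2]),
                beta = 10^(AMP_TRAIT_SD_LOG10 * z[3]),
                bg = 10^(BG_TRAIT_SD_LOG10 * z[4]))
  vseed <- if (visit == 1) subject$visit_seed1 else subject$visit_seed2
  seed <- derive_seed(vseed, "erp", design$task)
  data <- with_seed(derive_seed(seed, "background"),
                    sim_ongoing_eeg(n, fs, montage, mults))

  early <- if (design$task == "cvt") {
    list(lat0 = 0.12, width = 0.020, amp = 6)
  } else {
    list(lat0 = 0.20, width = 0.030, amp = 6)
  }
  lat_subj <- early$lat0 + 0.025 * z[5] +
    config$early_latency_shift_ms[[design$task]] / 1000 * sev
  amp_early_subj <- early$amp * exp(0.15 * z[7])
  amp_lpp_subj <- 4 * exp(0.3 * z[6] - 0.3 * config$lpp_amplitude_shift * sev)
  topo_early <- montage_topography(montage, 0, 0.3, 0.7, 0.1)
  topo_lpp <- montage_topography(montage, 0, -0.3, 0.7, 0.1)

  with_seed(derive_seed(seed, "templates"), {
    for (i in seq_len(nrow(design$trials))) {
      onset <- design$trials$onset_s[i]
      s0 <- round(onset * fs) + 1
      idx <- s0:min(n, s0 + round(1.0 * fs))
      t_rel <- (idx - s0) / fs
      lat <- lat_subj + stats::rnorm(1, 0, 0.006)
      a_e <- amp_early_subj * exp(stats::rnorm(1, 0, 0.15))
      a_l <- amp_lpp_subj * exp(stats::rnorm(1, 0, 0.20))
      shape <- a_e * exp(-(t_rel - lat)^2 / (2 * early$width^2))
      in_lpp <- t_rel >= 0.4 & t_rel <= 0.8
      lpp <- numeric(length(t_rel))
      lpp[in_lpp] <- a_l * sin(pi * (t_rel[in_lpp] - 0.4) / 0.4)
      data[, idx] <- data[, idx] + topo_early %o% shape + topo_lpp %o% lpp
    }
  })

  events <- simulate_behavior(subject, design, config, visit)
  events$sample <- round(events$onset_s * fs) + 1L
  list(recording = new_recording(data, fs, montage$label), events = events)
}

#' Inject artifacts with ground truth
#'
#' Adds a configurable number of artifacts of each kind at random positions:
#' `spike` (brief high-amplitude transient), `flat_high` (amplitude held above
#' 400 uV for more than a second), `drift` (slow high-amplitude ramp) and
#' `broadband_power` (segment amplitude scaled x4, i.e. power x16, exceeding
#' the 8x channel-mean power criterion). Each artifact affects one randomly
#' chosen channel.
#'
#' @param recording an `eeg_recording`.
#' @param counts named list/vector: number of artifacts per kind (default 0).
#' @param seed integer seed.
#' @return list with `recording` (modified copy) and `truth` (data.frame
#'   `start_sample`, `end_sample`, `channel`, `kind`; zero rows if no
#'   artifacts were requested).
#' @export
inject_artifacts <- function(recording, counts = list(), seed = 1L) {
  kinds <- c("spike", "flat_high", "drift", "broadband_power")
  cnt <- stats::setNames(rep(0L, length(kinds)), kinds)
  cnt[names(counts)] <- as.integer(unlist(counts))
  if (any(cnt < 0)) stopf("artifact counts must be >= 0")
  fs <- recording$fs
  n <- n_samples(recording)
  nch <- nrow(recording$data)
  data <- recording$data
  truth <- list()
  with_seed(derive_seed(seed, "artifacts"), {
    for (kind in kinds) {
      for (k in seq_len(cnt[[kind]])) {
        dur <- switch(kind,
          spike = stats::runif(1, 0.05, 0.15),
          flat_high = stats::runif(1, 1.5, 3),
          drift = stats::runif(1, 5, 10),
          broadband_power = stats::runif(1, 2, 4))
        len <- min(round(dur * fs), n - 2)
        start <- sample.int(n - len, 1)
        idx <- start:(start + len - 1)
        ch <- sample.int(nch, 1)
        sgn <- sample(c(-1, 1), 1)
        seg <- switch(kind,
          spike = {
            peak <- sgn * stats::runif(1, 500, 800)
            tri <- 1 - abs(seq(-1, 1, length.out = len))
            data[ch, idx] + peak * tri
          },
          flat_high = rep(sgn * stats::runif(1, 450, 600), len),
          drift = {
            ramp <- sgn * stats::runif(1, 400, 700) *
              (1 - abs(seq(-1, 1, length.out = len)))
            data[ch, idx] + ramp
          },
          broadband_power = {
            # scale the segment so its power clearly exceeds 8x the mean
            # channel power even after it inflates the cross-channel mean
            p_mean <- mean(rowMeans(data[, idx, drop = FALSE]^2))
            p_ch <- mean(data[ch, idx]^2)
            sqrt(20 * p_mean / max(p_ch, 1e-12)) * data[ch, idx]
          })
        data[ch, idx] <- seg
        truth[[length(truth) + 1]] <- data.frame(
          start_sample = start, end_sample = start + len - 1,
          channel = ch, kind = kind, stringsAsFactors = FALSE)
      }
    }
  })
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(start_sample = integer(), end_sample = integer(),
               channel = integer(), kind = character(), stringsAsFactors = FALSE)
  list(recording = new_recording(data, fs, recording$channels), truth = truth_df)
}
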