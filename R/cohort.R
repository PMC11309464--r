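#' Configuration of the synthetic two-visit cohort
#'
#' Collects the study conditions emulated by the simulator: group sizes, the
#' montage and sampling rate, the group-difference magnitudes per biomarker,
#' and the target test-retest correlation of subject traits across the two
#' visits. Effect sizes are Hedges' g of the group difference on the measure
#' the biomarker is read from (log10 band power for the spectral shifts,
#' seconds/percent for behaviour); latency and reaction-time shifts are given
#' directly in milliseconds as reported group mean differences.
#'
#' Defaults reproduce the MCI-vs-control contrasts the pipeline is built
#' around: elevated theta (g ~ +0.45), suppressed slow-beta (g ~ -0.66),
#' delayed early ERP component (+9 ms in the vigilance task, +21 ms in the
#' recognition task), reduced late positive potential (g ~ -0.7), slower
#' responses (+55 ms / +117 ms) and lower accuracy (-5 / -7 percentage points).
#'
#' @param n_hc,n_mci group sizes (>= 2).
#' @param n_channels montage size (default 20, 10-20 system).
#' @param fs sampling rate in Hz.
#' @param resting_duration_s eyes-closed resting recording length in seconds.
#' @param theta_shift,beta_shift effect size (Hedges' g) of the MCI shift of
#'   log10 band power in theta (3-7 Hz, positive = elevated) and slow-beta
#'   (13-20 Hz, negative = suppressed).
#' @param early_latency_shift_ms named vector `c(cvt=, sir=)`: group latency
#'   delay of the early ERP component in ms.
#' @param lpp_amplitude_shift effect size of the late-positive-potential
#'   amplitude reduction (positive number = reduction).
#' @param rt_shift_ms named vector `c(cvt=, sir=)`: group reaction-time slowing in ms.
#' @param accuracy_shift named vector `c(cvt=, sir=)`: accuracy reduction in
#'   percentage points.
#' @param test_retest_icc target intraclass correlation of subject traits
#'   across the two visits, in `[0, 1]`.
#' @param seed cohort master seed; all randomness flows from it.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_hc = 44, n_mci = 38, n_channels = 20, fs = 256,
                          resting_duration_s = 300,
                          theta_shift = 0.45, beta_shift = -0.66,
                          early_latency_shift_ms = c(cvt = 9, sir = 21),
                          lpp_amplitude_shift = 0.7,
                          rt_shift_ms = c(cvt = 55, sir = 117),
                          accuracy_shift = c(cvt = 5, sir = 7),
                          test_retest_icc = 0.85,
                          seed = 1L) {
  if (n_hc < 2 || n_mci < 2) stopf("need at least 2 subjects per group")
  if (fs <= 0) stopf("fs must be positive")
  if (test_retest_icc < 0 || test_retest_icc > 1) {
    stopf("test_retest_icc must be in [0, 1]")
  }
  structure(list(
    n_hc = as.integer(n_hc), n_mci = as.integer(n_mci),
    n_channels = as.integer(n_channels), fs = fs,
    resting_duration_s = resting_duration_s,
    theta_shift = theta_shift, beta_shift = beta_shift,
    early_latency_shift_ms = early_latency_shift_ms,
    lpp_amplitude_shift = lpp_amplitude_shift,
    rt_shift_ms = rt_shift_ms, accuracy_shift = accuracy_shift,
    test_retest_icc = test_retest_icc, seed = as.integer(seed),
    montage = default_montage(n_channels)
  ), class = "cohort_config")
}

#' Generate the subject table of a synthetic cohort
#'
#' Draws the latent disease-severity trait of every subject (MCI: normal with
#' mean 1 and SD 0.3; controls: 0), per-subject and per-visit realization
#' seeds, and a synthetic cognitive outcome (an MMSE-like score whose one-year
#' change is negatively coupled to severity) used by the prognostic analysis.
#' The severity trait is identical across a subject's visits: repeatability is
#' carried by the trait, visit-to-visit noise by the visit seeds.
#'
#' @param config a [cohort_config()].
#' @return data.frame of class `eeg_cohort` with columns `id`, `group`,
#'   `severity`, `subject_seed`, `visit_seed1`, `visit_seed2`,
#'   `mmse_baseline`, `mmse_change`.
#' @export
make_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_hc + config$n_mci
  group <- factor(c(rep("HC", config$n_hc), rep("MCI", config$n_mci)),
                  levels = c("HC", "MCI"))
  with_seed(derive_seed(config$seed, "cohort"), {
    severity <- ifelse(group == "MCI", stats::rnorm(n, 1, 0.3), 0)
    mmse_baseline <- round(pmin(30, ifelse(group == "MCI",
                                           stats::rnorm(n, 27.5, 1.8),
                                           stats::rnorm(n, 29.5, 0.6))))
    mmse_change <- round(-1.5 * severity + stats::rnorm(n, 0, 1.0))
    out <- data.frame(
      id = sprintf("S%03d", seq_len(n)), group = group, severity = severity,
      subject_seed = vapply(seq_len(n), function(i)
        derive_seed(config$seed, "subject", i), 1L),
      visit_seed1 = vapply(seq_len(n), function(i)
        derive_seed(config$seed, "visit", i, 1), 1L),
      visit_seed2 = vapply(seq_len(n), function(i)
        derive_seed(config$seed, "visit", i, 2), 1L),
      mmse_baseline = mmse_baseline, mmse_change = mmse_change,
      stringsAsFactors = FALSE
    )
  })
  class(out) <- c("eeg_cohort", "data.frame")
  out
}

# One subject's trait vector: standard-normal traits drawn from the subject
# seed, blended with visit-specific draws so that the across-visit correlation
# of each trait equals test_retest_icc (internal).
subject_traits <- function(subject, visit, config, n_traits = 12L) {
  icc <- config$test_retest_icc
  z_subj <- with_seed(derive_seed(subject$subject_seed, "traits"),
                      stats::rnorm(n_traits))
  vseed <- if (visit == 1) subject$visit_seed1 else subject$visit_seed2
  z_vis <- with_seed(derive_seed(vseed, "traits"), stats::rnorm(n_traits))
  sqrt(icc) * z_subj + sqrt(1 - icc) * z_vis
}
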