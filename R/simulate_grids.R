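# Grid-level and feature-level cohort generators.
#
# The signal-level simulator (simulate_resting / simulate_erp_session) is the
# full emulation of a recording session; these generators emulate the same
# cohorts one level up, directly at the per-subject analysis grids
# (channels x frequency log10-PSD, channels x time ERP amplitude) and at the
# 12-predictor feature table. They share the latent-severity model and make
# large replication studies (permutation-test calibration, effect-recovery and
# classifier checks) affordable.
#
# Between-subject variability is decomposed into five components mirroring the
# spatial/spectral correlation of scalp measures: a global offset, a
# per-channel offset, a per-frequency-block (or time-block) offset, a
# channel-by-block interaction, and independent cell noise. Group effects are
# injected as a mean shift over a cell mask, scaled so that the Hedges' g of
# the single-channel mask-window measure equals the configured effect size;
# the mask-averaged (CBA) measure then shows a small aggregation gain, as
# channel-level and cluster-level group contrasts do in scalp data.

default_grid_components <- function(space) {
  if (space == "channel_frequency") {
    # log10 PSD units
    c(global = 0.075, channel = 0.06, block = 0.085, chanblock = 0.055,
      cell = 0.027)
  } else {
    # microvolts
    c(global = 1.00, channel = 0.75, block = 0.90, chanblock = 0.65,
      cell = 0.50)
  }
}

# SD of the mask-mean (CBA) measure under the component model (internal)
grid_cba_sd <- function(sd, mask_channels, mask_bins, n_channels, block_of) {
  n_mc <- length(mask_channels)
  blocks <- block_of[mask_bins]
  wb <- table(blocks) / length(mask_bins)
  sqrt(sd[["global"]]^2 +
         sd[["channel"]]^2 / n_mc +
         sd[["block"]]^2 * sum(wb^2) +
         sd[["chanblock"]]^2 * sum(wb^2) / n_mc +
         sd[["cell"]]^2 / (n_mc * length(mask_bins)))
}

# smooth default baselines (internal)
grid_baseline <- function(space, n_channels, n_bins, times = NULL) {
  if (space == "channel_frequency") {
    f <- seq_len(n_bins)
    shape <- -1.0 * log10(f) + 0.35 * exp(-(f - 10)^2 / 8)  # 1/f + alpha bump
    matrix(rep(shape, each = n_channels), n_channels, n_bins) + 0.5
  } else {
    t <- times %||% seq(-0.2, by = 1 / 256, length.out = n_bins)
    shape <- 3 * exp(-(t - 0.15)^2 / (2 * 0.05^2)) +
      2.5 * ifelse(t >= 0.4 & t <= 0.8, sin(pi * (t - 0.4) / 0.4), 0)
    matrix(rep(shape, each = n_channels), n_channels, n_bins)
  }
}

#' Default grid effects for the resting-state PSD cohort
#'
#' MCI shifts of log10 resting PSD: theta (3-7 Hz) elevated and slow-beta
#' (13-20 Hz) suppressed over all channels, with effect sizes expressed as
#' Hedges' g of the per-channel band measure.
#'
#' @param theta_es,beta_es effect sizes (g) for the theta elevation and
#'   slow-beta suppression.
#' @param n_channels montage size.
#' @return list of effect descriptors for [simulate_stat_grids()].
#' @export
resting_grid_effects <- function(theta_es = 0.49, beta_es = -0.70,
                                 n_channels = 20) {
  list(
    list(name = "theta", channels = seq_len(n_channels), bins = 3:7, es = theta_es),
    list(name = "slow_beta", channels = seq_len(n_channels), bins = 13:20, es = beta_es)
  )
}

#' Default grid effects for an ERP task cohort
#'
#' MCI amplitude differences on the channels x time grid over `[-0.2, 0.8]` s:
#' an early-window difference (the signature of the delayed early component)
#' and a reduced late positive potential, with windows and effect sizes
#' mirroring the group contrasts the analysis is designed to detect.
#'
#' @param task `"cvt"` or `"sir"`.
#' @param n_bins number of time bins (default 256 at 256 Hz).
#' @return list of effect descriptors for [simulate_stat_grids()].
#' @export
erp_grid_effects <- function(task = c("cvt", "sir"), n_bins = 256) {
  task <- match.arg(task)
  t <- seq(-0.2, by = 1 / 256, length.out = n_bins)
  win_bins <- function(lo, hi) which(t >= lo & t <= hi)
  fronto_central <- c(4, 5, 6, 9, 10, 11)   # F3 Fz F4 C3 Cz C4
  centro_parietal <- c(9, 10, 11, 14, 15, 16) # C3 Cz C4 P3 Pz P4
  if (task == "cvt") {
    list(
      list(name = "early", channels = fronto_central,
           bins = win_bins(0.082, 0.141), es = -1.0),
      list(name = "lpp", channels = centro_parietal,
           bins = win_bins(0.379, 0.508), es = -0.7)
    )
  } else {
    list(
      list(name = "early", channels = fronto_central,
           bins = win_bins(0.137, 0.199), es = -0.97),
      list(name = "lpp", channels = centro_parietal,
           bins = win_bins(0.379, 0.445), es = -0.73)
    )
  }
}

#' Simulate per-subject analysis grids for a two-group cohort
#'
#' Draws per-subject channels x bins grids (log10 PSD or ERP amplitude) from
#' the component model described above, optionally at two visits with a
#' configurable test-retest correlation of all subject-level components.
#' Effects are added to the MCI group scaled by each subject's latent severity.
#'
#' @param n_hc,n_mci group sizes.
#' @param space `"channel_frequency"` (20 x 40 by default) or `"channel_time"`
#'   (20 x 256 over `[-0.2, 0.8]` s).
#' @param n_channels,n_bins grid dimensions.
#' @param effects list of effect descriptors (`name`, `channels`, `bins`, `es`);
#'   see [resting_grid_effects()] / [erp_grid_effects()]. Empty list = null cohort.
#' @param sd_components named numeric vector of between-subject SDs
#'   (`global`, `channel`, `block`, `chanblock`, `cell`); defaults depend on `space`.
#' @param block_bins width of the trait blocks along the bin axis.
#' @param test_retest_icc across-visit correlation of subject components.
#' @param n_visits 1 or 2.
#' @param seed integer seed.
#' @return object of class `grid_cohort`: list with `visits` (list of
#'   subjects x channels x bins arrays), `labels`, `severity`, `effects`
#'   (with the injected `delta` and cell masks), `space`, `dims`, `channels`.
#' @export
simulate_stat_grids <- function(n_hc = 44, n_mci = 38,
                                space = c("channel_frequency", "channel_time"),
                                n_channels = 20,
                                n_bins = if (space == "channel_frequency") 40 else 256,
                                effects = resting_grid_effects(n_channels = n_channels),
                                sd_components = NULL,
                                block_bins = if (space == "channel_frequency") 4 else 8,
                                test_retest_icc = 1, n_visits = 1, seed = 1L) {
  space <- match.arg(space)
  sd <- sd_components %||% default_grid_components(space)
  n <- n_hc + n_mci
  labels <- factor(c(rep("HC", n_hc), rep("MCI", n_mci)), levels = c("HC", "MCI"))
  block_of <- ceiling(seq_len(n_bins) / block_bins)
  n_blocks <- max(block_of)
  mu <- grid_baseline(space, n_channels, n_bins)
  montage <- default_montage(n_channels)

  # Effect sizes are defined on the single-channel band measure (the band mean
  # at one channel), matching how channel-level group contrasts are reported;
  # the cluster-aggregated (CBA) measure then shows a small aggregation gain
  # whose size depends on the cross-channel correlation.
  effects <- lapply(effects, function(ef) {
    ef$delta <- ef$es * grid_cba_sd(sd, ef$channels[1], ef$bins, n_channels,
                                    block_of)
    ef$mask <- cbind(channel = rep(ef$channels, times = length(ef$bins)),
                     bin = rep(ef$bins, each = length(ef$channels)))
    ef
  })

  icc <- test_retest_icc
  draw_components <- function(rng_seed) {
    with_seed(rng_seed, list(
      g = stats::rnorm(n),
      ch = matrix(stats::rnorm(n * n_channels), n, n_channels),
      bl = matrix(stats::rnorm(n * n_blocks), n, n_blocks),
      cb = array(stats::rnorm(n * n_channels * n_blocks), c(n, n_channels, n_blocks))
    ))
  }
  shared <- draw_components(derive_seed(seed, "grids", "shared"))
  severity <- with_seed(derive_seed(seed, "grids", "severity"),
                        ifelse(labels == "MCI", stats::rnorm(n, 1, 0.3), 0))

  visits <- vector("list", n_visits)
  for (v in seq_len(n_visits)) {
    vis <- draw_components(derive_seed(seed, "grids", "visit", v))
    mix <- function(a, b) sqrt(icc) * a + sqrt(1 - icc) * b
    g <- mix(shared$g, vis$g); chn <- mix(shared$ch, vis$ch)
    bl <- mix(shared$bl, vis$bl); cb <- mix(shared$cb, vis$cb)
    arr <- array(0, c(n, n_channels, n_bins))
    cell_noise <- with_seed(derive_seed(seed, "grids", "cells", v),
                            array(stats::rnorm(n * n_channels * n_bins, 0, sd[["cell"]]),
                                  c(n, n_channels, n_bins)))
    for (s in seq_len(n)) {
      field <- mu +
        sd[["global"]] * g[s] +
        sd[["channel"]] * matrix(chn[s, ], n_channels, n_bins) +
        sd[["block"]] * matrix(bl[s, block_of], n_channels, n_bins, byrow = TRUE) +
        sd[["chanblock"]] * cb[s, , block_of] +
        cell_noise[s, , ]
      if (labels[s] == "MCI") {
        for (ef in effects) {
          field[ef$mask] <- field[ef$mask] + ef$delta * severity[s]
        }
      }
      arr[s, , ] <- field
    }
    dimnames(arr) <- list(NULL, montage$label, NULL)
    visits[[v]] <- arr
  }

  structure(list(visits = visits, labels = labels, severity = severity,
                 effects = effects, space = space,
                 dims = c(n_channels, n_bins), channels = montage$label,
                 sd_components = sd, seed = seed),
            class = "grid_cohort")
}

DEFAULT_PREDICTORS <- c("EEG-PSDrel", "EEG-PSDabs",
                        "3CVT-cluster-1", "3CVT-cluster-2", "3CVT-Latency",
                        "SIR-cluster-1", "SIR-cluster-2", "SIR-Latency",
                        "RT-3CVT", "PC-3CVT", "RT-SIR", "PC-SIR")

DEFAULT_FEATURE_ES <- c(
  "EEG-PSDrel" = -0.70, "EEG-PSDabs" = 0.49,
  "3CVT-cluster-1" = -1.0, "3CVT-cluster-2" = -0.7, "3CVT-Latency" = 0.35,
  "SIR-cluster-1" = -0.97, "SIR-cluster-2" = -0.73, "SIR-Latency" = 0.86,
  "RT-3CVT" = 1.29, "PC-3CVT" = -0.42, "RT-SIR" = 0.57, "PC-SIR" = -0.28)

#' Simulate the 12-predictor feature table directly
#'
#' Feature-level emulation of the cohort for classifier and reliability
#' calibration: each of the 12 predictors is the configured effect size times
#' the subject's latent severity plus correlated unit-variance noise (block
#' correlation within measurement modality plus a weaker correlation across
#' all features). With two visits, severity is a fixed trait and the noise is
#' split into shared and visit-specific parts according to the test-retest
#' correlation. Disease-effect expression is partly state-dependent: at
#' baseline it varies mildly between subjects, and at follow-up it is partly
#' regressed toward zero (`followup_expression`) with additional state noise
#' (`expression_sd`). This limits the reliability of a composite score below
#' the reliability of its inputs and makes follow-up classification harder
#' than baseline classification, as observed in longitudinal biomarker
#' cohorts. A synthetic cognitive outcome change, negatively coupled to
#' severity, is included for the prognostic analysis.
#'
#' @param n_hc,n_mci group sizes.
#' @param effect_sizes named 12-vector of per-feature effect sizes (Hedges' g
#'   scale); defaults to the standard MCI contrasts.
#' @param rho_within noise correlation among features of the same modality.
#' @param rho_between noise correlation among features of different modalities.
#' @param followup_expression mean multiplicative expression of the disease
#'   effect at the follow-up visit (1 = fully stable).
#' @param expression_sd SD of the follow-up state fluctuation of expression.
#' @param test_retest_icc across-visit correlation of the noise component.
#' @param n_visits 1 or 2.
#' @param seed integer seed.
#' @return list with `visits` (list of data.frames: `subject`, `visit`,
#'   `label`, then the 12 predictors), `labels`, `severity`, `outcome`
#'   (`subject`, `mmse_change`).
#' @export
simulate_feature_table <- function(n_hc = 44, n_mci = 38,
                                   effect_sizes = DEFAULT_FEATURE_ES,
                                   rho_within = 0.3, rho_between = 0.25,
                                   followup_expression = 0.7,
                                   expression_sd = 0.5,
                                   test_retest_icc = 0.85,
                                   n_visits = 1, seed = 1L) {
  p <- length(DEFAULT_PREDICTORS)
  stopifnot(length(effect_sizes) == p)
  n <- n_hc + n_mci
  labels <- factor(c(rep("HC", n_hc), rep("MCI", n_mci)), levels = c("HC", "MCI"))
  blocks <- c(1, 1, 2, 2, 2, 3, 3, 3, 4, 4, 5, 5)
  sigma <- outer(blocks, blocks, function(a, b)
    ifelse(a == b, rho_within, rho_between))
  diag(sigma) <- 1
  cs <- chol(sigma)
  icc <- test_retest_icc
  rmvn <- function(rng_seed) {
    with_seed(rng_seed, matrix(stats::rnorm(n * p), n, p) %*% cs)
  }
  severity <- with_seed(derive_seed(seed, "features", "severity"),
                        ifelse(labels == "MCI", stats::rnorm(n, 1, 0.3), 0))
  shared <- rmvn(derive_seed(seed, "features", "shared"))
  expr_base <- with_seed(derive_seed(seed, "features", "expression"),
                         1 + 0.3 * stats::rnorm(n))
  subj <- sprintf("S%03d", seq_len(n))
  visits <- vector("list", n_visits)
  for (v in seq_len(n_visits)) {
    eps <- sqrt(icc) * shared + sqrt(1 - icc) * rmvn(derive_seed(seed, "features", v))
    expression <- if (v == 1) expr_base else {
      followup_expression * expr_base +
        expression_sd * with_seed(derive_seed(seed, "features", "state", v),
                                  stats::rnorm(n))
    }
    vals <- eps + (severity * expression) %o% unname(effect_sizes)
    df <- data.frame(subject = subj, visit = v, label = labels,
                     stringsAsFactors = FALSE, check.names = FALSE)
    df[DEFAULT_PREDICTORS] <- as.data.frame(vals)
    visits[[v]] <- df
  }
  outcome <- with_seed(derive_seed(seed, "features", "outcome"), data.frame(
    subject = subj,
    mmse_change = round(-1.5 * severity + stats::rnorm(n, 0, 1.0)),
    stringsAsFactors = FALSE))
  list(visits = visits, labels = labels, severity = severity, outcome = outcome)
}
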