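test_that("resting simulation is reproducible and physiologically scaled", {
  tc <- tiny_cohort(duration = 10)
  r1 <- simulate_resting(tc$cohort[1, ], 1, tc$config)
  r2 <- simulate_resting(tc$cohort[1, ], 1, tc$config)
  expect_identical(r1$data, r2$data)
  expect_lt(max(abs(r1$data)), 150)  # microvolts, physiological range
  expect_equal(dim(r1$data), c(20, 10 * 256))
  # different subjects get different recordings
  r3 <- simulate_resting(tc$cohort[2, ], 1, tc$config)
  expect_false(identical(r1$data, r3$data))
})

test_that("with trait ICC 1 and equal visit seeds the two visits are identical", {
  tc <- tiny_cohort(duration = 6, test_retest_icc = 1)
  subj <- tc$cohort[1, ]
  subj$visit_seed2 <- subj$visit_seed1
  v1 <- simulate_resting(subj, 1, tc$config)
  v2 <- simulate_resting(subj, 2, tc$config)
  expect_identical(v1$data, v2$data)
})

test_that("null configuration produces no systematic group difference in band power", {
  # all effect shifts zero: the group-mean theta power should differ only by
  # sampling noise
  n_sig <- 0L
  reps <- 8
  for (r in seq_len(reps)) {
    cfg <- cohort_config(n_hc = 8, n_mci = 8, resting_duration_s = 12,
                         theta_shift = 0, beta_shift = 0, seed = 400 + r)
    coh <- make_cohort(cfg)
    theta <- vapply(seq_len(nrow(coh)), function(i) {
      p <- compute_psd(simulate_resting(coh[i, ], 1, cfg), "absolute")
      mean(band_power(p)[, "Theta"])
    }, numeric(1))
    p <- t.test(theta[coh$group == "MCI"], theta[coh$group == "HC"])$p.value
    if (p < 0.01) n_sig <- n_sig + 1L
  }
  expect_lte(n_sig, 1L)
})

test_that("configured spectral effect sizes are recovered as Hedges' g", {
  reps <- 18
  gs <- t(vapply(seq_len(reps), function(r) {
    cfg <- cohort_config(n_hc = 16, n_mci = 16, resting_duration_s = 20,
                         theta_shift = 0.45, beta_shift = -0.66, seed = 500 + r)
    coh <- make_cohort(cfg)
    bp <- t(vapply(seq_len(nrow(coh)), function(i) {
      b <- band_power(compute_psd(simulate_resting(coh[i, ], 1, cfg), "absolute"))
      c(mean(b[, "Theta"]), mean(b[, "SlowBeta"]))
    }, numeric(2)))
    mci <- coh$group == "MCI"
    c(hedges_g(bp[mci, 1], bp[!mci, 1]), hedges_g(bp[mci, 2], bp[!mci, 2]))
  }, numeric(2)))
  # |bias| of the mean recovered g vs configured, within Monte-Carlo error
  expect_lt(abs(mean(gs[, 1]) - 0.45), 0.20)
  expect_lt(abs(mean(gs[, 2]) - (-0.66)), 0.20)
  # direction always as configured on the replicate means
  expect_gt(mean(gs[, 1]), 0)
  expect_lt(mean(gs[, 2]), 0)
})

test_that("band-power test-retest ICC tracks the configured trait ICC", {
  cfg <- cohort_config(n_hc = 40, n_mci = 2, resting_duration_s = 15,
                       test_retest_icc = 0.85, seed = 31)
  coh <- make_cohort(cfg)
  hc <- coh[coh$group == "HC", ]
  theta <- vapply(1:2, function(v) {
    vapply(seq_len(nrow(hc)), function(i) {
      mean(band_power(compute_psd(simulate_resting(hc[i, ], v, cfg),
                                  "absolute"))[, "Theta"])
    }, numeric(1))
  }, numeric(nrow(hc)))
  icc <- icc_alpha(theta[, 1], theta[, 2])
  expect_lt(abs(icc - 0.85), 0.15)
})

test_that("behavioural reaction-time shifts match the configured group slowing", {
  reps <- 20
  diffs <- t(vapply(seq_len(reps), function(r) {
    cfg <- cohort_config(n_hc = 40, n_mci = 40, seed = 600 + r)
    coh <- make_cohort(cfg)
    des_cvt <- make_erp_design("cvt", 60, seed = r)
    des_sir <- make_erp_design("sir", 60, seed = r)
    rt <- t(vapply(seq_len(nrow(coh)), function(i) {
      c(behavioral_summary(simulate_behavior(coh[i, ], des_cvt, cfg))$mean_rt_s,
        behavioral_summary(simulate_behavior(coh[i, ], des_sir, cfg))$mean_rt_s)
    }, numeric(2)))
    mci <- coh$group == "MCI"
    1000 * c(mean(rt[mci, 1]) - mean(rt[!mci, 1]),
             mean(rt[mci, 2]) - mean(rt[!mci, 2]))
  }, numeric(2)))
  expect_lt(abs(mean(diffs[, 1]) - 55), 20)   # vigilance task: +55 ms
  expect_lt(abs(mean(diffs[, 2]) - 117), 30)  # recognition task: +117 ms
})

test_that("accuracy is reduced in the MCI group", {
  cfg <- cohort_config(n_hc = 40, n_mci = 40, seed = 77)
  coh <- make_cohort(cfg)
  des <- make_erp_design("sir", 80, seed = 1)
  acc <- vapply(seq_len(nrow(coh)), function(i) {
    behavioral_summary(simulate_behavior(coh[i, ], des, cfg))$accuracy_pct
  }, numeric(1))
  expect_lt(mean(acc[coh$group == "MCI"]), mean(acc[coh$group == "HC"]))
})

test_that("artifact injection honours counts, bounds and determinism", {
  tc <- tiny_cohort(duration = 20)
  rec <- simulate_resting(tc$cohort[1, ], 1, tc$config)
  # zero artifacts: identity
  out0 <- inject_artifacts(rec, list(), seed = 1)
  expect_identical(out0$recording$data, rec$data)
  expect_equal(nrow(out0$truth), 0)
  # injected artifacts are recorded and within bounds
  out <- inject_artifacts(rec, list(spike = 2, flat_high = 1, drift = 1,
                                    broadband_power = 1), seed = 2)
  expect_equal(nrow(out$truth), 5)
  expect_true(all(out$truth$start_sample >= 1))
  expect_true(all(out$truth$end_sample <= ncol(rec$data)))
  # flat_high holds |amplitude| > 400 uV
  fh <- out$truth[out$truth$kind == "flat_high", ]
  seg <- out$recording$data[fh$channel, fh$start_sample:fh$end_sample]
  expect_true(all(abs(seg) > 400))
  expect_gt((fh$end_sample - fh$start_sample + 1) / rec$fs, 1)
  # determinism
  out2 <- inject_artifacts(rec, list(spike = 2, flat_high = 1, drift = 1,
                                     broadband_power = 1), seed = 2)
  expect_identical(out$recording$data, out2$recording$data)
})

test_that("the artifact scanner recovers injected flat and broadband artifacts", {
  tc <- tiny_cohort(duration = 20)
  hits <- 0L; total <- 0L
  for (r in 1:10) {
    rec <- simulate_resting(tc$cohort[1 + (r %% 6), ], 1, tc$config)
    out <- inject_artifacts(rec, list(flat_high = 1, broadband_power = 1),
                            seed = 100 + r)
    mask <- scan_artifacts(rec = out$recording)
    for (i in seq_len(nrow(out$truth))) {
      total <- total + 1L
      tr <- out$truth[i, ]
      overlap <- which(mask$window_start <= tr$end_sample &
                         mask$window_end >= tr$start_sample)
      flagged <- any(vapply(overlap, function(w)
        tr$channel %in% mask$flagged[[w]], logical(1)))
      if (flagged) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.9)
})
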