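test_that("baseline correction removes the pre-stimulus mean and is idempotent", {
  fs <- 256
  # constant offset
  ep <- make_epochs(array(5, c(2, 3, round(2.1 * fs))))
  out <- baseline_correct(ep)
  idx <- which(out$times >= -0.1 & out$times < 0)
  expect_equal(max(abs(out$data[, , idx])), 0)
  # linear ramp through zero at onset: slope 10 uV/s
  n <- round(2.1 * fs)
  times <- -0.8 + (seq_len(n) - 1) / fs
  ramp <- array(rep(10 * times, each = 2), c(1, 2, n))
  epr <- baseline_correct(make_epochs(ramp))
  onset <- which.min(abs(epr$times))
  # pre-stimulus mean of the ramp is -10 * 0.05 (midpoint of [-0.1, 0))
  expect_equal(epr$data[1, 1, onset], 10 * 0.05, tolerance = 0.05)
  # idempotence
  expect_equal(baseline_correct(epr)$data, epr$data, tolerance = 1e-12)
})

test_that("trial rejection applies the amplitude window and correctness filter", {
  fs <- 256
  n <- round(2.1 * fs)
  t_idx <- function(t) which.min(abs(-0.8 + (0:(n - 1)) / fs - t))
  data <- array(0, c(20, 2, n))
  # trials 1-2: 150 uV inside the scan window -> dropped
  data[1, 1, t_idx(0.3)] <- 150
  data[2, 2, t_idx(0.1)] <- -150
  # trial 3: 150 uV at 0.9 s, outside [-0.05, 0.7] -> retained
  data[3, 1, t_idx(0.9)] <- 150
  meta <- data.frame(trial_type = rep("target", 20),
                     correct = c(rep(TRUE, 16), rep(FALSE, 4)),
                     rt_s = 0.5)
  ep <- make_epochs(data, metadata = meta)
  kept <- reject_trials(ep)
  expect_equal(dim(kept$data)[1], 14)  # 20 - 4 incorrect - 2 over-amplitude
  # the out-of-window spike on trial 3 was retained
  expect_true(any(abs(kept$data) > 100))
  counts <- attr(kept, "rejection_counts")
  expect_equal(unname(counts["amplitude"]), 2)
  expect_equal(unname(counts["response"]), 4)
  # NA correctness counts as missing response
  meta$correct[3] <- NA
  kept2 <- reject_trials(make_epochs(data, metadata = meta))
  expect_equal(dim(kept2$data)[1], 13)
})

test_that("averaging enforces the minimum-trial rule and is exact", {
  data <- array(rep(1:8, each = 1), c(8, 1, 64))
  ep <- make_epochs(data, t0 = -0.1)
  expect_error(average_erp(ep), class = "eegmci_too_few_trials")
  # identical trials average to any trial
  data9 <- array(2.5, c(9, 1, 64))
  avg <- average_erp(make_epochs(data9, t0 = -0.1))
  expect_true(all(avg$waveform == 2.5))
  expect_equal(avg$n_trials, 9)
  # law of large numbers: averaging N=50 iid trials shrinks sigma ~ 1/sqrt(N)
  set.seed(50)
  noise <- array(rnorm(50 * 1 * 512), c(50, 1, 512))
  avg_n <- average_erp(make_epochs(noise, t0 = -0.1))
  expect_lt(abs(sd(avg_n$waveform) - 1 / sqrt(50)) / (1 / sqrt(50)), 0.2)
})

test_that("component measurement finds peak, latency and mean with the tie rule", {
  fs <- 256
  n <- round(2.1 * fs)
  times <- -0.8 + (0:(n - 1)) / fs
  gauss <- 4 * exp(-(times - 0.15)^2 / (2 * 0.02^2))
  wf <- rbind(gauss, 0.5 * gauss)
  erp <- structure(list(waveform = wf, times = times, n_trials = 20,
                        stimulus_type = "target", channels = c("Cz", "Pz")),
                   class = "erp_average")
  m <- measure_component(erp, "P1")
  expect_lt(max(abs(m$latency_s - 0.15)), 1 / fs)
  expect_equal(m$peak_uv, c(4, 2), tolerance = 1e-3)
  # flat zero waveform: latency = window start by the first-maximum rule
  flat <- structure(list(waveform = matrix(0, 1, n), times = times,
                         n_trials = 20, stimulus_type = "x", channels = "Cz"),
                    class = "erp_average")
  mf <- measure_component(flat, "LPP")
  expect_equal(mf$mean_uv, 0)
  expect_equal(mf$latency_s, times[which(times >= 0.4)[1]])
  # linearity: halving the waveform halves the mean amplitude
  half <- erp; half$waveform <- erp$waveform / 2
  expect_equal(measure_component(half, "P1")$mean_uv,
               measure_component(erp, "P1")$mean_uv / 2)
})

test_that("the grand average weights subjects equally", {
  fs <- 256
  n <- 128
  times <- (0:(n - 1)) / fs
  mk <- function(w, nt) structure(list(waveform = matrix(w, 1, n), times = times,
                                       n_trials = nt, stimulus_type = "t",
                                       channels = "Cz"), class = "erp_average")
  expect_equal(grand_average(list(mk(3, 10)))$waveform, matrix(3, 1, n))
  expect_true(all(grand_average(list(mk(2, 10), mk(-2, 40)))$waveform == 0))
  # trial-weighted oracle differs when trial counts differ
  trial_weighted <- (2 * 10 + (-2) * 40) / 50
  expect_false(isTRUE(all.equal(0, trial_weighted)))
  e1 <- mk(1, 10); e2 <- mk(1, 10); e2$times <- times + 1
  expect_error(grand_average(list(e1, e2)), "time axes")
})

test_that("behavioural summaries compute accuracy and correct-only reaction time", {
  ev <- data.frame(phase = "test", trial_type = "target",
                   correct = c(rep(TRUE, 282), rep(FALSE, 94)),
                   rt_s = 0.5)
  b <- behavioral_summary(ev)
  expect_equal(b$accuracy_pct, 75.0)
  ev2 <- data.frame(phase = "test", trial_type = "t",
                    correct = c(TRUE, TRUE), rt_s = c(0.4, 0.6))
  expect_equal(behavioral_summary(ev2)$mean_rt_s, 0.5)
  ev3 <- data.frame(phase = "test", trial_type = "t",
                    correct = c(FALSE, FALSE), rt_s = c(0.4, NA))
  b3 <- behavioral_summary(ev3)
  expect_equal(b3$accuracy_pct, 0)
  expect_true(is.na(b3$mean_rt_s))
  expect_error(behavioral_summary(ev3, classes = "absent"), "scoreable")
})

test_that("the configured latency delay is recovered by the latency feature", {
  # Group difference of the per-subject P1 peak latency at Cz (the pipeline's
  # latency predictor) under a configured 25 ms delay.
  shift_one <- function(seed) {
    cfg <- cohort_config(n_hc = 40, n_mci = 40,
                         early_latency_shift_ms = c(cvt = 25, sir = 25),
                         seed = seed)
    coh <- make_cohort(cfg)
    des <- make_erp_design("cvt", 60, seed = seed)
    lats <- c(); grp <- c()
    for (i in seq_len(nrow(coh))) {
      sim <- simulate_erp_session(coh[i, ], des, cfg)
      ep <- baseline_correct(epoch_recording(sim$recording, sim$events))
      kept <- reject_trials(ep)
      avg <- tryCatch(average_erp(kept, "target"),
                      eegmci_too_few_trials = function(e) NULL)
      if (!is.null(avg)) {
        m <- measure_component(avg, "P1")
        lats <- c(lats, m$latency_s[m$channel == "Cz"])
        grp <- c(grp, as.character(coh$group[i]))
      }
    }
    1000 * (mean(lats[grp == "MCI"]) - mean(lats[grp == "HC"]))
  }
  shifts <- vapply(61:62, shift_one, numeric(1))
  # One sample of recovery tolerance plus the sampling error of the group
  # latency difference itself: the subject-level latency trait has SD 25 ms,
  # so a 40 v 40 group difference carries SE 25*sqrt(2/40) ~ 5.6 ms, and the
  # mean over 2 replicate cohorts ~ 4.5 ms.
  expect_lt(abs(mean(shifts) - 25), 1000 / 256 + 2 * 4.5)
})
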