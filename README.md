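# eegmci

Composite EEG/ERP biosignatures of mild cognitive impairment (MCI), end to
end: from continuous multichannel EEG to a single reliability-tested MCI
score.

Cognitive decline leaves reproducible traces in scalp electrophysiology —
resting-state power shifts from fast to slow rhythms (theta 3–7 Hz elevated,
slow-beta 13–20 Hz suppressed), event-related potentials (ERPs) show a
delayed early component and a reduced late positive potential (LPP), and
behaviour slows. None of these separates patients from controls on its own.
`eegmci` implements the full analysis chain that aggregates them:

1. **Preprocessing** — zero-phase band-pass (0.3–49 / 0.3–40 Hz) + 60 Hz
   notch; 2-s moving-window artifact detection (power > 8× channel mean;
   |amplitude| > 400 µV for half a window; peak-to-peak > 500 µV); channel
   interpolation vs segment exclusion; extended-infomax ICA decontamination
   with a pluggable component classifier (reject brain-probability < 10%).
2. **Spectral features** — Kaiser-windowed (β = 6) 1-s epochs, unscaled
   `psd(f) = (1/Fs)·2|X(f)|²` at 1-Hz bins 1–40, three-epoch smoothing,
   log₁₀, session averaging; absolute and relative dialects; band powers and
   the theta-to-alpha ratio.
3. **ERP features** — epoching (−0.8 to +1.3 s), 100-ms baseline, 100 µV /
   correctness trial rejection, ≥ 9-trial averages, P1/P200/LPP component
   measures, grand averages, behavioural summaries.
4. **Cluster statistics** — cell-wise t maps on 20 × 40 channel-frequency or
   20 × 256 channel-time grids; edge-connectivity clusters (p < 0.01,
   minimum size 2 / 20 cells) with statistical size
   `tsize = Σ t`; a 1000-iteration max-`|tsize|` permutation null
   (exhaustive below n = 10); significance at the 95th percentile; CBA
   (cluster-based aggregated) subject measures.
5. **Composite score** — the 12 canonical predictors
   (`EEG-PSDrel`, `EEG-PSDabs`, `3CVT-cluster-1/2`, `3CVT-Latency`,
   `SIR-cluster-1/2`, `SIR-Latency`, `RT-3CVT`, `PC-3CVT`, `RT-SIR`,
   `PC-SIR`), a standardized linear SVM (C = 1, score > 0 ⇒ MCI), rank AUC /
   accuracy / balanced accuracy, stratified 5-fold cross-validation,
   split-sample validation across visits, SVM-weight and
   permutation-feature importance.
6. **Reliability & prognosis** — Hedges' g (with the `1 − 3/(4n−9)`
   correction), Cronbach-alpha ICC (`2(1 − (s₁²+s₂²)/s²_sum)`), Pearson r,
   and the four-quadrant baseline-score vs cognitive-decline summary.

Because the pipeline's inputs are clinical recordings that cannot be
redistributed, the package ships calibrated synthetic cohort generators at
three levels (continuous EEG with ground-truth artifacts; per-subject
analysis grids; the 12-predictor feature table), emulating a two-visit
HC/MCI study with configurable effect sizes and test-retest correlation.
They are tested, first-class code — see the methods vignette
(`vignettes/eegmci-methods.Rmd`) for the models and every calibration
constant.

## Worked example

```r
library(eegmci)

cfg <- run_config(
  cohort = cohort_config(n_hc = 10, n_mci = 10, resting_duration_s = 24,
                         theta_shift = 2, beta_shift = -2,
                         early_latency_shift_ms = c(cvt = 60, sir = 60),
                         lpp_amplitude_shift = 2.5, seed = 3),
  n_perm = 80, min_size_time = 8,
  designs = list(cvt = make_erp_design("cvt", 100, seed = 3),
                 sir = make_erp_design("sir", 80, seed = 4)),
  seed = 3)
report <- run_baseline(cfg)

names(report$modalities)
#> [1] "psd_rel"  "psd_abs"  "erp_cvt"  "performance_cvt"  "erp_sir"  "performance_sir"
round(report$effect_sizes[c("RT-3CVT", "3CVT-Latency", "EEG-PSDabs")], 2)
#>      RT-3CVT 3CVT-Latency   EEG-PSDabs
#>         2.71         1.38         2.31
report$classifier$cv
#> <eval_report> AUC 0.990 | accuracy 90.0% | BAC 90.0% (n = 10 MCI / 10 HC)
```

This runs the whole signal-level chain on a small, strongly separated
synthetic cohort: each subject's resting EEG and two task sessions are
simulated, artifact-laden segments repaired or excluded, PSD and ERP grids
extracted, cluster permutation tests run per modality, the 12-predictor
table assembled, and the SVM cross-validated. The effect sizes are the
Hedges' g of each predictor between groups (reaction time slower, latency
delayed, theta power elevated in MCI — the configured directions), and the
classifier separates the groups essentially perfectly at this effect
strength. `run_longitudinal(cfg)` adds the two-visit analysis: paired
cluster tests of within-subject change, per-predictor ICC/r, split-sample
validation with per-visit evaluation, score test-retest reliability and the
prognostic quadrants.

At the defaults (`cohort_config()` with effect sizes at the scale such MCI
cohorts report, 44 + 38 subjects), the calibrated generators reproduce the
study conditions the analysis is designed for: ~90–95% of 40 v 40 cohorts
yield a significant cluster over an injected region, cross-validated
AUC ≈ 0.9, held-out AUC ≈ 0.84 at baseline falling to ≈ 0.75 at follow-up,
and a score test-retest ICC ≈ 0.9.

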