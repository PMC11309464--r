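---
title: "Methods: EEG/ERP biosignatures of mild cognitive impairment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG/ERP biosignatures of mild cognitive impairment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Mild cognitive impairment (MCI) is the prodromal stage between healthy aging
and dementia. Electrophysiology offers inexpensive, non-invasive markers of
the synaptic dysfunction that precedes structural neurodegeneration: in
resting-state EEG, cognitive decline shifts spectral power from fast to slow
rhythms (theta up, beta down, elevated theta-to-alpha ratio); in stimulus
tasks it delays early event-related potential (ERP) components, shrinks the
late positive potential (LPP), slows responses, and lowers accuracy. No
single measure separates MCI from healthy controls well, so `eegmci`
implements the full chain from raw multichannel EEG to a *composite* MCI
score: preprocessing, spectral and ERP feature extraction, data-driven
feature definition by 2-D cluster-based permutation testing, a 12-predictor
linear-SVM score, and its test-retest reliability over a follow-up visit.

Because no public recording satisfies all of the pipeline's input contracts,
the package ships synthetic cohort generators at three levels of abstraction
(continuous EEG, per-subject analysis grids, and the feature table). They are
first-class, tested code: every downstream stage is exercised and calibrated
against them.

## Preprocessing

* **Filtering.** Zero-phase (forward-backward) order-4 Butterworth band-pass,
  0.3--49 Hz for resting data and 0.3--40 Hz for ERP data, followed by a
  zero-phase 60 Hz IIR biquad notch (Q = 30). Zero-phase application matters
  because component latency is a biomarker. The filter realization is a
  design choice; the band edges are analysis constants.
* **Artifact scan.** A 2-s moving window with 50% overlap (1-s hop) flags a
  channel in a window when (i) its window power exceeds 8x the mean window
  power across channels, or (ii) |amplitude| stays above 400 uV for more than
  half the window, or the within-window peak-to-peak range exceeds 500 uV.
  "Change within the segment" is read as peak-to-peak range -- the most
  direct reading. The thresholds are deliberately conservative: on clean
  synthetic EEG fewer than 1% of windows are flagged.
* **Repair vs exclusion.** A window with exactly one flagged channel has that
  channel interpolated from its nearest montage neighbours (mean of the four
  closest unflagged channels -- a light-weight stand-in for spherical
  splines, adequate for a 20-channel montage). Windows with two or more
  flagged channels are excluded. Because windows overlap, a sample is
  excluded if *any* covering window is excluded, and interpolation applies on
  the union of single-channel flagged windows; this sample-level resolution
  of overlapping verdicts is an interpretation and is centralized in
  `repair_or_reject()`.
* **Epoching.** ERP epochs span -0.8 to +1.3 s around stimulus onset
  (`round(2.1 * fs)` samples). Epochs that underrun/overrun the recording or
  intersect an exclusion interval are dropped.
* **ICA decontamination.** Full-rank extended-infomax ICA (natural-gradient
  ascent with a per-component sub/super-Gaussian switch and learning-rate
  annealing; no dimension reduction), fitted on the continuous recording for
  resting data and on concatenated epochs for ERP data, on an evenly strided
  subsample of at most 20k time points. The component classifier is
  *injectable*: any function mapping a decomposition to per-component brain
  probabilities can be used, and every component with brain probability
  below 10% is rejected before remixing. The bundled
  `heuristic_component_classifier()` scores components by excess kurtosis,
  low-frequency power fraction and single-channel loading concentration; it
  is a deliberately simple heuristic, not a re-implementation of pre-trained
  classifiers. If the ICA iteration fails to stabilize the data pass through
  unchanged with a warning flag -- decontamination must never silently
  corrupt data.

The pipeline order is fixed: filter, scan, repair, epoch, decontaminate.
Filtering before epoching avoids per-epoch filter transients.

## Spectral analysis

PSD follows a fixed recipe: 1-s epochs with 50% overlap; per epoch a Kaiser
window (beta = 6) and an FFT of length `fs`; the unscaled density
`psd(f) = (1/Fs) * 2 |X(f)|^2` at the 1-Hz bins 1--40; linear averaging of
the three overlapping epochs centered on each non-overlapping epoch (edges
average what exists); log10; then averaging of the log values over the
session's non-overlapping epochs, skipping epochs that intersect excluded
intervals. A 5-minute session yields 300 averaging epochs. For the
*relative* dialect each bin is divided by the 1--40 Hz bin sum per channel
and epoch *before* smoothing; the normalization range is not uniquely
determined by convention, and 1--40 Hz keeps the absolute and relative
pipelines structurally parallel (recorded as an assumption). Band powers are
arithmetic means of log-PSD over the printed band bins, inclusive on both
edges even where bands overlap (delta and theta share 3 Hz, and so on) --
the historical definitions are reproduced verbatim rather than disjointed.
The theta-to-alpha ratio is the difference of mean log powers, i.e. the log
of the power ratio, consistent with the log-domain storage. PSD values below
1e-12 are floored before the log so degenerate inputs cannot produce
infinities.

## ERP analysis

Baseline correction subtracts the mean over the 100 ms before onset. Trials
are rejected when |amplitude| exceeds 100 uV on any channel within
[-50, 700] ms, or when the response is incorrect or missing; the two filters
are independent, so their order is immaterial. Per-subject averages need at
least 9 surviving trials; below that the acquisition is *excluded* via a
typed condition (`eegmci_too_few_trials`), never silently returned. Analyzed
stimulus classes are fixed: frequent targets in the vigilance task, novel
images in the recognition task (more trials survive for novel images, giving
more robust averages). Component windows default to P1 [80, 200] ms, P200
[130, 280] ms, LPP [400, 800] ms -- chosen inside the components' described
ranges and exposed as configuration, since exact windows are analysis
parameters that must be reproducible. Peak latency takes the *first* maximum
on ties, making the measure deterministic. Grand averages weight subjects
equally regardless of trial counts. Accuracy is the percentage of all
presented trials of the analyzed class answered correctly (non-responses
count as errors); mean reaction time uses correct trials only.

## Cluster-based permutation statistics

First-level statistics are two-sided pooled-variance Student's t tests per
cell of a channels x frequency (20 x 40 = 800 cells) or channels x time grid
(20 x 256 points over [-0.2, +0.8] s at 256 Hz; we treat the grid size as
exactly 20 x 256 = 5120 cells), or paired t tests for within-subject visit
changes. Zero-variance cells get t = 0, p = 1 with a warning. Cells with
p < 0.01 are grouped into connected components under *edge connectivity*,
read as 4-neighbour adjacency: two cells connect when they share a channel
and adjacent bins, or the same bin and adjacent channels. Scalp channels
have no canonical linear order, so channel adjacency defaults to consecutive
rows of the montage's anterior-to-posterior, left-to-right ordering and can
be overridden with any symmetric adjacency matrix -- this is the central
interpretive decision of the module. Clusters mix only same-sign cells
(standard two-sided max-statistic control); components smaller than 2 cells
(channel-frequency) or 20 cells (channel-time, about 78 channel-ms) are
discarded, in the permutation null exactly as in the primary analysis. The
null records the largest |tsize| (sum of member t values) over 1000 label
shuffles preserving group sizes (sign flips for the paired design); with 10
or fewer subjects the relabelings are enumerated exhaustively instead. A
cluster's percentile is the percentage of null maxima at or below its
|tsize| (ties count as below); significance requires the 95th percentile.
Cluster-based aggregated (CBA) measures average a subject's grid over the
cluster's cells.

Because the primary labeling is exchangeable with the shuffled ones under
the null, the procedure's false-positive rate is ~5% by construction; the
test suite verifies 3--7% over 500 null cohorts.

## The composite score

The 12 predictors are: the CBA of the significant cluster of the relative
and of the absolute resting PSD analysis (when a modality has no significant
cluster, the highest-percentile cluster is used instead -- the fallback
exists precisely because one modality may fall just short); the CBAs of the
top two clusters of each ERP task; the early-component peak latency at a
configured channel per task (default Cz for the vigilance task and Fz for
the recognition task, following the midline channels with a prominent early
peak; `Pz` is available as the config alternative because reported channel
choices for this feature are inconsistent); and mean reaction time plus
accuracy per task. Subjects missing any modality are dropped (listwise
completeness).

The classifier is a soft-margin linear SVM (box constraint C = 1, the
standard default) on predictors standardized by *training* mean and SD;
scores are oriented so positive means MCI and classification happens at
score 0. Evaluation reports the rank-statistic AUC (midranks on ties),
accuracy, and balanced accuracy (mean of sensitivity and specificity) at the
fixed operating point, plus the Hedges' g separation of the score
distributions. Cross-validation uses stratified folds with standardization
and fitting strictly inside training folds; split validation requires
disjoint train/test subject sets and evaluates each visit with that visit's
diagnosis labels. Feature selection (the cluster masks) is computed on
baseline data for both visits, mirroring a selection-on-all-baseline-data
protocol; the optimism this can introduce relative to selection inside
training folds only is a documented property of that protocol. Predictor
importance is reported two ways: |weight| as a percentage of the total
absolute weight, and permutation feature importance (shuffling one predictor
column 100 times without refitting and averaging the drop in AUC, accuracy
and balanced accuracy).

## Reliability and prognosis

Hedges' g uses the pooled-SD standardized mean difference with the
small-sample correction `J = 1 - 3/(4n - 9)`. Test-retest consistency uses
Cronbach's alpha at k = 2 measurements, `alpha = 2 (1 - (s1^2 + s2^2) /
s_sum^2)` -- the consistency-type ICC, equivalent to ICC(3,k); the
absolute-agreement family is deliberately out of scope, and the choice is
recorded because "alpha equations" do not pin down the variant. Note the
identity `alpha = 2r/(1+r)`: reported alpha/r pairs must satisfy it, which
is a useful sanity check on any reliability table. The prognostic analysis
cross-tabulates baseline classification (score > 0) against subsequent
cognitive decline (outcome change below 0 by default; the threshold is
configuration) into four quadrants and correlates score with outcome change.

## The synthetic cohort

**Signal level.** Continuous EEG is 1/f background noise plus coherent
band-limited oscillators (theta 5 Hz, alpha 10 Hz strongest occipitally,
beta 16.5 Hz) with smooth scalp topographies. All sources are multiplied by
slow lognormal burst envelopes (~1--2 s timescale): cortical rhythms wax and
wane, and this non-Gaussianity is also what makes the sources identifiable
by ICA -- purely Gaussian surrogates are not. Amplitudes sit in a
physiological range (background ~7 uV RMS, peaks well under 100 uV).
Subject traits (oscillator amplitudes, latencies, behavioural offsets) are
standard-normal draws blended across visits so their correlation equals the
configured test-retest ICC; the latent MCI severity (normal, mean 1, SD 0.3;
0 in controls) is a fixed trait.

Spectral effects are injected as oscillator power shifts of
`es * 0.2 * severity` in log10 units, where 0.2 is the designed
between-subject SD of log band power; because band edge bins are partly
background-dominated, the injected shift is divided by the measured band
expression fraction (0.80 for theta, 0.95 for slow-beta) so that configured
effect sizes are recovered 1:1 as Hedges' g. ERP trials superimpose a
Gaussian early peak (vigilance ~120 ms, recognition ~200 ms,
fronto-central) and a half-cosine LPP plateau (400--800 ms,
centro-parietal); MCI delays the early peak by the configured milliseconds
times severity and scales the LPP down. The subject latency trait SD is
25 ms, chosen so the default latency shifts (9 and 21 ms) correspond to
latency effect sizes of ~0.35 and ~0.85. Reaction times are a subject offset
(between-subject SD 43 ms vigilance / 205 ms recognition, so the default
55/117 ms slowings give effect sizes ~1.3/~0.6) plus a lognormal per-trial
component; accuracy is Bernoulli per trial with a subject-level rate.
One caveat follows from the design: a 40 v 40 group difference in measured
latency inherits an SE of ~5.6 ms from the latency trait alone, so
single-cohort latency recovery is verified to sampling tolerance, not to one
sample.

**Grid level.** For replication studies (type-I error over hundreds of null
cohorts, detection rates over 100 effect cohorts) the package simulates the
per-subject analysis grids directly. Between-subject variability decomposes
into five components -- global, per-channel, per-frequency/time-block,
channel-by-block, and independent cell noise -- mirroring the strong
spatial/spectral correlation of scalp measures. Effects are mean shifts over
a cell mask scaled so that the *single-channel* mask-window measure has the
configured Hedges' g (channel-level and cluster-level contrasts nearly
coincide in scalp data, and the CBA then shows a small aggregation gain,
~0.1 here). The component SDs are frozen at (0.075, 0.06, 0.085, 0.055,
0.027) log10 units with 4-bin blocks for the frequency grid and (1.0, 0.75,
0.9, 0.65, 0.5) uV with 8-bin (31 ms) blocks for the time grid; they were
chosen once so the generator meets its contract -- cluster recovery of
paper-scale effects in >= 80% of 40 v 40 cohorts, CBA effect sizes within
+/-0.2 of configuration, false-positive rate within [0.03, 0.07]. Under
these defaults, detection of at least one injected region is ~90-95% in both
spaces; the narrow LPP-only window alone is detected in only ~60% of
cohorts, which is the expected power of a 0.7-effect on a short window at
this sample size.

**Feature level.** The 12 predictors are effect size times severity plus
correlated unit-variance noise (0.3 within modality, 0.25 across). Effect
*expression* is partly state-dependent: ~N(1, 0.09) per subject at baseline,
and at follow-up regressed to 0.7x with additional state noise (SD 0.5).
This is what keeps composite-score reliability below the reliability of its
inputs -- with a perfectly stable group separation, Cronbach's alpha of the
score would sit near 0.97 regardless of the noise ICC -- and it reproduces
the qualitative longitudinal pattern of such cohorts: cross-validated AUC
~0.9 at baseline, held-out AUC ~0.84-0.87 falling to ~0.75-0.77 at
follow-up, score ICC ~0.88-0.90 with r ~0.8. The synthetic cognitive outcome declines with
severity (`round(-1.5 * severity + N(0,1))`), putting the score-vs-decline
correlation near 0.45.

**What the generators do not model.** No volume conduction or dipolar
forward model, no ocular/cardiac artifact morphology (artifacts are injected
as abstract kinds with ground truth), no task-difficulty or fatigue
dynamics, no label noise in the diagnosis, and the two reported MCI-to-HC
reversions at follow-up are not modelled -- labels are constant across
visits. Passing tests therefore demonstrate that the *procedures* are
correct and calibrated on data with realistic first- and second-order
structure, not that the pipeline's clinical numbers transfer to any real
cohort.

## Numerical choices and degenerate inputs

Log floors at 1e-12; zero-variance first-level cells get t = 0, p = 1;
latency ties resolve to the earliest sample; permutation percentiles count
ties as below; exhaustive enumeration replaces sampling for n <= 10;
standardization guards zero-SD predictors by unit scale; the ICA identity
fallback carries a warning attribute; zero surviving epochs warn and yield
an empty epoch set; fewer than 9 trials raise a typed exclusion condition.
All randomness flows from explicit integer seeds through a deterministic
seed-derivation hash, so every artifact is bit-reproducible from
(configuration, seed).

## Problem sizes used by the tests

The statistical calibration suites run at the scales their claims are stated
for (type-I error: 500 null cohorts of 20 v 20 at 200 permutations; effect
recovery: 100 cohorts of 40 v 40; classifier calibration: cohorts of
44 v 38 with a 29 + 18 two-visit test set). The signal-level end-to-end
pipeline tests use a compact, strongly separated mechanics cohort (10 v 10,
abbreviated schedules, shortened resting recordings, proportionally reduced
minimum channel-time cluster size) -- scales chosen so the full path is
exercised with ample statistical headroom -- while signal-level *generator*
calibration (spectral g recovery, ICC propagation, behavioural shifts) runs
on reduced-duration recordings at 16--40 subjects per group, with
Monte-Carlo-consistent tolerances.

## Known limitations

Channel interpolation is neighbour-averaging, not spherical splines; the
heuristic component classifier is a placeholder interface, not a validated
artifact classifier; the linear chain is only a default channel adjacency;
no TFCE or cluster-mass alternatives; no probability calibration of SVM
scores; reliability is limited to the two-visit consistency ICC. These match
the intended scope: a complete, calibrated reference implementation of the
composite-biosignature analysis chain.
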