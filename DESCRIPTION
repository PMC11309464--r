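Package: eegmci
Title: EEG and ERP Biosignatures of Mild Cognitive Impairment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: End-to-end analysis of electroencephalographic (EEG) biosignatures
    of mild cognitive impairment (MCI). Implements preprocessing of continuous
    multichannel EEG (band-pass and notch filtering, moving-window artifact
    detection, channel interpolation or segment exclusion, ICA-based
    decontamination with a pluggable component classifier), resting-state power
    spectral density with band aggregation and the theta-to-alpha ratio,
    event-related potential (ERP) epoching and component measurement,
    two-dimensional cluster-based permutation statistics on channel-by-frequency
    and channel-by-time grids with cluster-based aggregated (CBA) measures, a
    twelve-predictor linear support-vector-machine composite MCI score with
    cross-validation and split-sample validation, and test-retest reliability
    analysis (Hedges' g, Pearson correlation, Cronbach-alpha ICC). A synthetic
    two-visit cohort simulator generates resting and task EEG with configurable
    group effects, behavioural responses, and ground-truth artifacts so that
    every stage of the pipeline can be exercised and calibrated without access
    to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
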