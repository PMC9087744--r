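Package: ictalwave
Title: Multimodal Analysis of Hippocampal Seizures: Recruitment, Phase
    Coupling, and Traveling Waves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for joint analysis of microelectrode-array
    electrophysiology and multicellular calcium imaging of acute
    seizures. Implements calcium-transient onset detection and
    recruitment-order reliability statistics (Spearman, Kendall's W with
    a permutation null), band-limited phase and amplitude analysis of
    the local field potential with high-gamma burst and multiunit spike
    detection, circular hypothesis tests (Watson-Williams, common-median,
    Hodges-Ajne omnibus), plane-fit estimation of seizure discharge
    traveling-wave speed and direction across an electrode grid,
    sliding-window multimodal feature extraction (including the
    phase-locking value and calcium line length), and bagged
    regression-tree ensembles that predict traveling-wave speed from
    single-site multimodal features with out-of-bag permutation
    importance. A seeded synthetic multimodal seizure generator with
    known ground truth supports end-to-end validation by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    rpart,
    jsonlite,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
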