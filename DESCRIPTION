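Package: amuseBCI
Title: Auditory ERP Brain-Computer Interface Analysis with Eyes-Open and
    Eyes-Closed Conditions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Offline analysis pipeline for auditory event-related potential
    (ERP) brain-computer interfaces based on the six-speaker AMUSE oddball
    paradigm, recorded under alternating eyes-open (EO) and eyes-closed (EC)
    conditions. Provides stimulus-schedule construction and bookkeeping, a
    ground-truth-labeled synthetic EEG generator (N200/P300 templates,
    1/f background noise, condition-dependent occipital alpha, ocular
    artifacts), Chebyshev-II band-pass preprocessing with epoching and
    baseline correction, peak-to-peak and variance-based artifact rejection
    with EOG regression, interval-mean features with shrinkage-regularized
    linear discriminant decoding scored by chronological cross-validated
    AUC, condition-switch transfer simulations with incremental retraining,
    and ERP statistics (grand averages, signed r-squared maps, N200/P300
    peak extraction, exact Wilcoxon signed-rank, Holm correction, exact
    binomial preference test, Likert/SAM rating summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'artifact.R'
    'erp.R'
    'features.R'
    'io.R'
    'lda.R'
    'montage.R'
    'paradigm.R'
    'pipeline.R'
    'preprocess.R'
    'profile.R'
    'ratings.R'
    'reference.R'
    'synthesize.R'
    'tests-stats.R'
    'transfer.R'
    'utils.R'
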