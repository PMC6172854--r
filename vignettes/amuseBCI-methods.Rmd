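---
title: "amuseBCI: models, design choices and validation strategy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{amuseBCI: models, design choices and validation strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

Auditory event-related-potential (ERP) brain-computer interfaces present a
rapid stream of word stimuli from spatially arranged loudspeakers; the user
attends one word (the *target*), and a classifier detects the attended
stimulus from single-trial EEG. This package implements the complete
offline analysis for the six-speaker AMUSE oddball paradigm recorded under
alternating *eyes-open* (EO) and *eyes-closed* (EC) runs: stimulus
scheduling and bookkeeping, preprocessing, ocular-artifact handling,
shrinkage-LDA decoding with chronological cross-validation, a
condition-switch transfer simulation, ERP statistics, and a synthetic EEG
generator that stands in for the original recordings so that every stage
of the pipeline can be exercised, tested and benchmarked without any data
download.

## Paradigm model

A session is 18 runs, strictly alternating EO/EC. Each run holds six
trials; within a trial each of the six word stimuli is played 15 times at
a stimulus onset asynchrony (SOA) of 250 ms (90 stimuli per trial, class
ratio 1:5). Within a run, each stimulus is the cued target of exactly one
trial. A full session therefore contains, per condition, 54 trials with
810 target and 4050 non-target events. `buildSessionSchedule()` realizes
pseudo-randomization as three seeded uniform shuffles: the within-trial
stimulus sequence (constrained to 15 repetitions each), the target order
within each run (a permutation of 1–6), and a session-wide
stimulus-to-speaker assignment. No constraint on immediate stimulus
repetitions is imposed — the paradigm states none, and inventing one
would change overlap statistics.

Only relative onsets matter to the analysis, so inter-trial structure is
summarized by configurable gaps: 6 s between trials (covering the spoken
cue), 10 s between runs, and a 3 s lead-in before the first stimulus so
the first epoch's pre-stimulus window exists.

## Synthetic subjects and recordings

`makeSubjectProfile()` draws per-condition N200/P300 latencies and
amplitudes from normal distributions whose centers and spreads are the
published 12-subject group statistics shipped in
`referencePeakTable()` (EO: N200 201 ms / −1.53 µV, P300 690 ms /
1.71 µV; EC: 206 / −1.59, 523 / 1.95; SDs 27.6/0.96/158/0.43 and
27.4/0.87/161/0.82). Latencies are truncated to the epoch window and
amplitudes keep their sign by reflection. Everything else is a documented
generator default, not a published fact:

* **Component shape.** Each component is Gaussian in time
  (σ = 40 ms for the N200, 110 ms for the P300, i.e. ~94 ms and ~260 ms
  FWHM) on a Gaussian spatial map over an idealized planar 63-channel
  montage — unit weight at FCz for the N200, at Pz for the P300,
  falloff σ = 0.45 head-radius units. Exact scalp maps are not published;
  these qualitatively reproduce the fronto-central negativity and parietal
  positivity.
* **Class attenuation.** Non-target epochs carry the same components
  attenuated by 0.6 (N200) and 0.15 (P300). These are free parameters;
  together with the noise level they were calibrated **once** so that the
  default-profile five-fold chronological-CV AUC lands in the 0.75–0.80
  band, and not revisited.
* **Background noise.** 1/f-shaped noise (white noise through a standard
  pink-noise IIR approximation), pairwise inter-channel correlation 0.3
  via a shared component, per-channel SD `noiseSdUV` (default 4 µV — the
  calibrated value), multiplied by a site-dependent scale
  (0.8 + 0.5·r², noisier at peripheral electrodes) and a slow two-tone
  amplitude modulation (periods ~20 s and ~75 s, ±40%). The site scale
  and modulation give per-channel and per-trial variance distributions a
  realistic spread; without them the percentile-based variance criteria —
  which compare against 3 × (P90 − P10) of a variance distribution —
  degenerate on homogeneous synthetic data.
* **Alpha.** 10 Hz occipital activity (map centered at Oz), amplitude
  modulated, scaled per condition (defaults 2 µV EO, 8 µV EC — the
  classic alpha blocking asymmetry).
* **Eye artifacts.** Poisson-timed biphasic blinks (~300 ms, default peak
  100 µV at Fp2, opposite sign at the periocular channel EOGvu, decaying
  scalp projection) and step-like saccades (~200 ms, antisymmetric on
  F9/F10, random direction). Default rates: blinks 0.12 Hz (EO) /
  0.15 Hz (EC), saccades 0.06 / 0.15 Hz — more ocular activity with eyes
  closed, where no fixation cross suppresses drift. Every injection is
  logged with ground truth for recovery tests.

What the generator deliberately does **not** emulate: biophysical head
volume conduction, auditory-cortex dynamics of word processing,
single-trial latency jitter, non-stationary ERP habituation, or muscle and
line-noise artifacts. Passing tests therefore demonstrate the *analysis
pipeline's* correctness and the qualitative study phenomena, not
physiological realism of the simulated EEG.

## Preprocessing

The fixed order is: zero-phase Chebyshev II band-pass [0.5, 8] Hz at
1 kHz → decimation to 100 Hz → epoching [−200, 1200) ms → baseline
subtraction over [−200, 50] ms (closed interval, 26 samples at 100 Hz;
epochs have 140 samples at −200, −190, …, 1190 ms). The published band
is [0.5, 8] Hz with a Chebyshev Type II filter; order and attenuation are
unstated, so the package uses two order-5 sections (high-pass + low-pass),
40 dB stopband each, applied forward-backward. The transition bands are
design choices: stopband edges at `lowHz/4` and `2·highHz`. Measured on
sinusoids, the cascade is within 0.1% of unity at 2–4 Hz, ~0.93 at the
0.5/8 Hz edges, and ≥60 dB down at 20 Hz; an isolated P300-like bump
(σ = 110 ms) passes with gain ≈ 0.99 and an N200-like bump (σ = 40 ms)
with gain ≈ 0.98. A wider high-pass transition (stop edge at `lowHz/2`)
attenuates slow P300-like bumps by ~12% — an error that would directly
bias the peak-recovery validation — which is why the narrower edge is the
default. One caveat of so low a corner: the section's slowest modes ring
for tens of seconds, so filtered values near in time can depend weakly
(≤1% of signal range) on how much context the filter saw; the test suite
checks interior stability at that tolerance.

Event onsets are kept in milliseconds and snapped to the nearest sample
at epoching (≤5 ms error at 100 Hz). Whether the original analysis
filtered each run separately is unstated; the package filters the whole
continuous recording once.

## Artifact handling

*Minmax_60* (`minmaxFlag`) flags epochs whose peak-to-peak range strictly
exceeds 60 µV on any of Fp1, Fp2, F7, F8, F9, F10. Pipeline **P1** is
exactly this flagging — data are never modified. Pipeline **P2** first
regresses the bipolar channels EOGh = F9 − F10 and EOGv = Fp2 − EOGvu out
of every scalp channel (ordinary least squares on all concatenated epoch
samples — the stationary-eye-pattern assumption; an intercept is included
in the fit and only the EOG components are subtracted), then applies the
variance criteria, then Minmax_60. The variance criteria read the
published rules literally: a channel is rejected when its per-epoch SD is
below 0.5 µV (variance < 0.25 µV²) in more than 10% of epochs, or when
its variance (mean of per-epoch variances) exceeds 3 × (P90 − P10) of the
channel-variance distribution; trials are flagged analogously with one
variance per epoch. The alternative reading (P90 + 3 × (P90 − P10)) is
available via arguments. The literal rule only behaves when the healthy
variance distribution has real spread — one reason the generator models
site-dependent noise. Variance criteria pool both conditions (the
per-condition alternative is a subset call away). Flagged epochs are
**retained** for classification by default (so condition comparisons use
identical epoch counts) and excluded only from artifact statistics;
`dropFlagged = TRUE` selects the other behavior. An arbitrary
epoch-cleaning function can be slotted in place of the EOG regression via
the `cleaner` argument, which is the extension point for ICA-based
cleaners; a pretrained ICA-component classifier is out of scope here.

## Features, classifier, evaluation

Each epoch is reduced to per-channel means over eight fixed intervals
([100,190], [191,300], [301,450], [451,560], [561,700], [701,850],
[851,1000], [1001,1200] ms), channel-major — 504 dimensions for 63
channels. The classifier is a binary LDA whose pooled within-class
covariance (divisor n − 2) is shrunk toward νI, ν = tr(Σ̂)/d, with the
analytic Ledoit–Wolf-type intensity

γ* = Σᵢⱼ V̂ar(Sᵢⱼ) ⁄ Σᵢⱼ (Sᵢⱼ − ν δᵢⱼ)², clipped to [0, 1],

so that γ → 0 as evidence accumulates and γ → 1 when the target is as
plausible as the sample covariance. Weights are w = Σ̃⁻¹(μ₊ − μ₋); the
bias centers the boundary between the class means. Performance is the
area under the ROC curve computed as the Mann–Whitney statistic with
midrank ties — the probability that a target outscores a non-target;
chance is 0.5. Cross-validation is five-fold *chronological*: trials (not
epochs) are cut into contiguous, time-ordered blocks, so no trial's
epochs straddle folds and no future data leaks backwards. Per-fold AUCs
are averaged unweighted (fold sizes are near-equal); pooling out-of-fold
scores instead is available via `aggregate = "pooled"`.

## Transfer simulation

`learningCurve()` draws m = 1…18 trials uniformly from a condition's
first 18, trains, and tests on one randomly chosen unseen trial of the
same condition, averaged over seeds. `transferExperiment()` simulates a
condition switch after 18 trials: per seed, the classifier trained on the
first 18 pre-condition trials is scored on a trial drawn (without
replacement) from the post-condition pool — trials 19–54 of the post
condition, keeping switch and stay scenarios symmetric — after which the
trial joins the training set and the classifier is retrained, for 36
steps. Twenty seeds is the default, matching the study protocol; whether
the original drew with or without replacement is unstated, and without
replacement was chosen so every post-transition trial is eventually seen.

## Statistics

Grand averages, signed r² maps (point-biserial correlation between the
binary label and amplitude, returned as sign(r)·r², positive where the
target mean exceeds the non-target mean, 0 where variance vanishes), and
N200/P300 peak extraction from per-subject target averages (raw windowed
extrema — minimum of FCz in [100, 300] ms, maximum of Pz in
[250, 900] ms; the windows are design choices covering all published
per-subject values, and no smoothing or local-maximum rule is applied).
The paired t-test wraps the classic statistic with n − 1 df. The Wilcoxon
signed-rank test is exact by full enumeration of all 2ⁿ sign assignments
(midranks for ties, zero differences dropped, n ≤ 25); the two-sided p is
twice the lower tail of the min-sum statistic, which reproduces the
published p = 0.0024 for W = 3 at n = 12. Holm's step-down correction is
delegated to `stats::p.adjust`. The preference test is the standard exact
binomial tail; for 9 of 12 subjects preferring one condition it yields
p = 299/4096 ≈ 0.073 — the corresponding published value (0.006) is not
reproducible under any standard convention we identified, so the package
reports the exact tail and asserts nothing about that number.
`summarizeRatings()` bundles the descriptive table, the four paired
t-tests, the preference test and the Holm correction across the five.

## Validation strategy, problem sizes, and known limitations

The test suite validates every operation against independent oracles
(explicit superposition sums, brute-force range scans, O(n²) AUC
enumeration, closed-form 2-D LDA, full sign-assignment enumeration,
hand-stepped Holm), plus the study-level properties on synthetic
sessions. Stochastic checks use reduced problem sizes chosen for
statistical resolution: 2–10-run sessions, reduced 12–16-channel montages
for the repeated-retraining experiments, 5–20 permutations or seeds per
null check; the acceptance script runs the full 18-run, 63-channel, 1 kHz
session.

Two structural facts about fast-SOA ERP analysis inform the validation
design:

* **Overlap bias.** With events every 250 ms and deterministic responses,
  the epoch average estimates the deviation of the target response from
  the *event-mean* response: every epoch contains the neighboring events'
  components at the same phase, and baseline correction over one full SOA
  period removes their mean. Measured peak amplitudes are therefore
  depressed by roughly the factor 1 − 1/6 − (5/6)·attenuation relative to
  the configured single-event template (≈ 35% at default attenuations).
  This is a property of the paradigm, not a pipeline defect — the
  published peak table itself was measured on overlapping data. The
  parameter-recovery validation consequently runs on sessions whose
  non-target attenuation is configured to zero, isolating the evoked
  components; under low noise the full pipeline then recovers configured
  latencies within 10 ms and amplitudes within ~12% (bounds: 20 ms /
  20%). Default attenuations are used everywhere else.
* **Chance-level control.** Permuting labels before chronological CV must
  yield AUC ≈ 0.5; this is the package's main guard against information
  leakage across folds and the quantity the acceptance script recomputes
  on the full session (20 permutations, per-condition CV, grand mean).

Known limitations: the generator's deterministic single-trial responses
make decoding easier at matched SNR than real EEG with latency jitter;
the planar montage distorts true inter-electrode distances at the head's
edge; the exact Wilcoxon implementation is memory-bound near n = 25; and
the Chebyshev high-pass's long impulse response makes results depend
(at the ≲1% level) on recording length around each epoch.
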