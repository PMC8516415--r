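---
title: "Automated sleep staging: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated sleep staging: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnostage)
```

This vignette is the package's own account of its method: the model and its
assumptions, the parameters that matter, what the synthetic generator does
and does not emulate, and the places where the design was genuinely open
and a choice had to be made.

## The staging model

Sleep staging is treated as per-epoch multiclass classification over the
five AASM stages W, N1, N2, N3 and R, in that canonical order everywhere a
matrix or an argmax appears. The approach is deliberately feature-based
rather than end-to-end learned: every input to the classifier is an
interpretable quantity a sleep scorer could inspect, which matters for a
field where algorithmic decisions are audited against visual scoring.

Assumptions worth stating explicitly:

* **Units.** Several features (standard deviation, IQR, absolute power)
  are amplitude-dependent, so inputs must be in microvolts. The EDF reader
  therefore trusts the physical-dimension header field, converts mV, and
  refuses anything else rather than guessing.
* **Complete epochs.** Scoring is defined on whole 30-s epochs; a trailing
  partial epoch is dropped, never padded.
* **No artifact rejection.** The pipeline runs on the raw (filtered)
  signal; the median-averaged Welch estimator is the only robustness
  mechanism. This mirrors how the classifier is meant to be deployed —
  artifact handling upstream would change the feature distributions.
* **One night = one normalization unit.** Smoothed features are z-scored
  within the night to absorb inter-individual EEG amplitude differences;
  nothing is ever normalized across nights.

## Parameters and defaults

| Parameter | Default | Unit | Why |
|---|---|---|---|
| analysis rate | 100 | Hz | all features are well below 50 Hz; keeps cost low |
| bandpass | 0.4–30 | Hz | the informative EEG band; removes drift and EMG bleed |
| epoch length | 30 | s | the AASM scoring unit |
| Welch segment | 5 | s | 0.20 Hz resolution; median over 11 segments per epoch |
| bands | slow 0.4–1, delta 1–4, theta 4–8, alpha 8–12, sigma 12–16, beta 16–30 | Hz | conventional clinical bands; they partition 0.4–30 so relative powers sum to 1 |
| centered window | 15 epochs (7.5 min) | epochs | triangular weights 0.125…1…0.125 |
| past window | 4 epochs (2 min) | epochs | trailing mean, strictly before the current epoch |
| boosting | 500 trees, depth 5, 90 leaves, 60% features | — | gap-aware selection (see below) |
| class weights | N1 2.2, N2 1, N3 1.2, R 1.4, W 1 | — | counteract stage imbalance (N2 ≈ half of a night, N1 ≈ 5%) |
| confidence threshold | 0.80 | — | defines the "high-confidence" stratum in reports |

The permutation entropy uses order 3 and delay 1, normalized by log 3! to
[0, 1]: order 3 is the standard choice for 30-s windows at 100 Hz, giving
2998 ordinal patterns per epoch — ample for a 6-cell histogram. Higuchi's
fractal dimension uses k_max = 10; both Petrosian and Higuchi variants are
kept as features since they respond to different aspects of signal
roughness.

Model selection minimizes `|acc_train − acc_test| + 4(1 − acc_test)` under
threefold cross-validation: accuracy dominates, but the train/test gap term
vetoes configurations that only look good in-sample. Class-weight search
instead maximizes the mean of accuracy and macro-F1 over the printed
324-point grid, because the weights exist precisely to trade a little
overall accuracy for minority-stage recall, which macro-F1 sees and
accuracy does not.

## Numerical choices

* **Welch.** 500-sample Hamming segments, 250-sample step, per-segment
  constant detrend, median across segments per frequency bin. Band power
  integrates bins whose center lies in `[low, high)`; the last band is
  closed at 30 Hz so the partition is exact and the six relative powers sum
  to 1 to machine precision.
* **Ratios and logs.** Power ratios are computed from relative powers with
  a `+1e-12` denominator guard; broadband power is reported as
  `log10(power + 1e-12)` for dynamic-range compression ahead of tree
  splits.
* **Degenerate epochs.** A constant epoch yields std = IQR = zero-crossings
  = Hjorth mobility = permutation entropy = Higuchi slope = 0 and finite
  values everywhere else; extraction fails loudly if any non-finite value
  survives.
* **Zero-crossings.** Strict sign changes; exact zeros inherit the previous
  sign, so a signal touching zero without crossing does not count.
* **Filtering.** The bandpass is a linear-phase Hamming FIR applied
  forward–backward (zero net phase, so features stay aligned with epoch
  boundaries), with transition widths min(low, 2 Hz) and 5 Hz; the
  convolution runs through FFT overlap-add, making 8-h nights cheap.
  Resampling is rational polyphase with an anti-alias FIR designed at the
  upsampled rate (~53 dB stopband); the library routine we would otherwise
  use carries an 11-tap anti-alias filter, far too weak for a 2.56×
  decimation.
* **Edges.** The centered smoothing window truncates at the night's edges
  and renormalizes its weights — padding would leak a fictitious
  "pre-lights-off" state into the first epochs. The trailing window falls
  back to the current epoch's value at epoch 1. Nights shorter than the
  centered window still process, with a warning, since short recordings
  (naps) are legitimate if degraded inputs.
* **Ties.** Probability argmax ties break toward the earlier canonical
  stage; scorer-reliability ties break toward the lower scorer index. Both
  are arbitrary but deterministic, which is what reproducibility needs.
* **Consensus ties.** The tie rule uses the most reliable scorer's label
  when it is among the tied top-voted stages. When it is not (possible only
  when the reliable scorer voted outside the tie), the tied stage earliest
  in canonical order is used instead, preserving the invariant that the
  consensus stage always carries a maximal vote count.
* **Transition convention.** With boundaries indexed between epochs *i* and
  *i+1*, epoch *e* is "around a transition" when a boundary exists in
  `[e−3, e+2]` — three epochs (1.5 min) of influence on each side. The
  3-min rule admits ±1-epoch variants; this one is symmetric in time and is
  the convention used consistently by mask, tests and reports.
* **Determinism.** One master seed derives per-night, per-channel, and
  per-scorer substreams through a small integer LCG kept below 2³¹, and the
  boosting backend runs single-threaded with a fixed seed, so every
  pipeline output reproduces bit-identically.

## The synthetic generator

The generator exists so that every module — I/O, preprocessing, features,
context, model, consensus, metrics — can be exercised end to end with known
ground truth. It emulates exactly the structure the features discriminate:

* **Hypnogram.** A five-stage Markov chain with strongly persistent stages
  (self-transition 0.60–0.89) whose long-run distribution gives realistic
  proportions (roughly 13% W, 7% N1, 44% N2, 17% N3, 19% R), started awake.
  A gentle exponential bias inflates transitions into N3 early in the night
  and into R late, reproducing the well-known night-long stage asymmetry
  that makes time-elapsed an informative covariate.
* **Signals.** Per epoch, Gaussian noise shaped in the frequency domain so
  the expected band-power composition follows the stage's profile, scaled
  to a stage- and channel-specific RMS amplitude. The default profiles
  encode the canonical signatures: delta-dominant high-amplitude N3 (60%
  delta target, 55 µV), a sigma bump in N2 (18%), alpha-rich wake (38%),
  low-amplitude mixed-frequency N1 and R on the EEG; slow-eye-movement and
  REM-rich EOG in W/N1/R; and a flat, beta-heavy EMG whose amplitude
  collapses in REM (4 µV vs 9–18 µV elsewhere) — muscle atonia.
* **Realism.** A generator whose stages are perfectly separable validates
  nothing: a classifier scores 100% with uniformly saturated confidence,
  and the confidence- and transition-stratified analyses become vacuous.
  Three mechanisms therefore perturb the clean targets, all chosen to
  mimic documented properties of real PSG: per-epoch log-normal jitter of
  the band profile (sd 0.4) and of the RMS amplitude (sd 0.2) — EEG band
  composition fluctuates substantially epoch to epoch within one stage —
  and a 50% blend of the *previous* stage's spectrum and amplitude into
  the first epoch after every stage change, since transitional epochs
  genuinely contain a mixture of both stages and are where human scorers
  and algorithms alike make most of their errors.
* **Scorers.** Imperfect human scorers are the truth corrupted per epoch at
  a configurable rate through an adjacent-stage confusion kernel with no
  self-transitions, so a scorer's expected disagreement with truth equals
  the corruption rate exactly.

What it does **not** emulate — and hence what passing tests do and do not
show: there are no discrete microevents (spindles, K-complexes, slow-wave
morphology), no artifacts, no within-stage spectral drift, no ambiguous
transitional epochs where human scorers genuinely disagree, and epochs are
spectrally independent given the stage. Synthetic stages are therefore far
more separable than clinical ones: the held-out benchmark validates that
the pipeline is wired correctly (features carry the stage information
through smoothing and the classifier to calibrated probabilities), not that
clinical-grade accuracy has been achieved. Claims about real PSG require
real PSG.

## Benchmark problem sizes

The package's end-to-end benchmark trains on 20 synthetic nights and
evaluates on 5 held-out nights of 960 epochs (8 h) each — 19,200 training
epochs, 190 features — which keeps a full run, generation through
evaluation, in the ten-minute range on a single core while remaining large
enough for stable median statistics. The test suite reuses a shared 120-epoch
night for unit-level checks and reserves the full-scale benchmark
for the acceptance suite.

## Known limitations

* The gradient-boosting backend is xgboost's histogram algorithm with
  leaf-wise growth; it matches the intended configuration (estimators,
  depth, leaves, feature fraction, per-stage weights) but is not
  tree-for-tree identical to other boosting libraries.
* Duplicating every training row leaves predicted stages unchanged but can
  perturb probabilities at the third decimal, a known property of
  histogram-based split finding.
* EDF support covers 16-bit continuous-recording EDF/EDF+ signals; EDF+
  annotations, discontinuous records and vendor formats are out of scope.
* Scoring below the 30-s resolution is out of scope; the minimum viable
  resolution of the spectral features would in any case be the 5-s Welch
  segment.
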