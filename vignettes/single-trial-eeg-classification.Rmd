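---
title: "Classifying fluid-intelligence groups from single-trial oddball EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying fluid-intelligence groups from single-trial oddball EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Fluid intelligence — the capacity for reasoning and novel problem solving —
is conventionally measured with Raven's Advanced Progressive Matrices
(RAPM), a 36-item non-verbal test scored 0–36. Subjects can be split into a
low-ability (LA) and a high-ability (HA) group by their score. During a
visual oddball task (a stream of frequent "standard" and rare "target"
stimuli), the attention-related evoked response over the midline electrodes
Fz, Cz and Pz differs between such groups, most strongly in the slow
(delta-band) components that carry the P300 complex. `wavefi` implements a
complete single-trial classification system around that observation: given
one unaveraged 600 ms epoch (−100 to +500 ms around a target stimulus,
250 Hz, three channels, microvolts), predict whether the subject belongs to
the LA or HA group.

Because no recordings are distributed with this package, a seeded synthetic
cohort generator stands in for the acquisition stage. It is first-class,
tested code: every property the pipeline claims is demonstrated against the
generator's known ground truth.

## Pipeline

1. **Preprocessing.** Continuous recordings are band-pass filtered to
   0.3–30 Hz with a second-order Butterworth filter (12 dB/octave per
   edge) applied forward–backward (`bandpass_filter()`). Zero-phase
   filtering was chosen so the evoked component's latency is not shifted;
   the one-way roll-off matches the stated hardware characteristic, and
   filter fidelity is deliberately not an acceptance surface. Epochs are
   cut as 25 pre-stimulus + 125 post-stimulus samples
   (`segment_epochs()`; 0-based half-open window, the stimulus-onset
   sample opens the post-stimulus side). Any epoch with an absolute
   amplitude of 90 µV or more on any channel is rejected
   (`reject_artifacts()`). Subjects are screened (scores outside
   mean ± 3 sample SD excluded) and split LA/HA at a cutoff score of 24
   (`assign_groups()`); the published score table fixes HA ≥ 24 and
   LA ≤ 23 in both content conditions, so 24 is the boundary consistent
   with it, and it is exposed as a parameter.

2. **Haar decomposition.** Each channel is decomposed to level 4 with the
   orthonormal Haar pair (`haar_dwt()`), giving bands A4, D4, D3, D2, D1.
   A 600 ms epoch at 250 Hz has 150 samples, which `2^4` does not divide;
   epochs are truncated to their first 144 samples (the last 24 ms are
   dropped) so the transform is exact, Parseval holds to machine
   precision, and A4 and D4 carry exactly nine coefficients per channel.
   The analysis step takes non-overlapping sample pairs
   (`a_k = (x_{2k-1}+x_{2k})/√2`, `d_k = (x_{2k-1}-x_{2k})/√2`), which
   for Haar equals periodized convolution with stride 2 — padding-free
   and verifiable against an explicit orthonormal analysis matrix, which
   the test suite does. Band labels follow the conventional dyadic
   halving of the filtered band's 30 Hz top frequency
   (`band_frequency_map()`): A4 = 0–1.875 Hz (delta low),
   D4 = 1.875–3.75 Hz (delta high), up to D1 = 15–30 Hz. This is a
   labelling layer — the physical dyadic bands at a 250 Hz sampling rate
   are wider — and `f_top` is configurable.

3. **Features.** Two descriptors (`build_feature_matrix()`):
   *statistical wavelet features* (SWF) — per channel and band, relative
   energy `Er` (band energy over total across all five bands), mean,
   standard deviation (n−1), kurtosis and skewness (population
   standardized moments, normal → 3, no bias correction), and wavelet
   energy entropy `e = −Σ pᵢ log₂ pᵢ` with `pᵢ` the normalised squared
   coefficients (the standard wavelet-domain entropy in the EEG
   literature; the convention only needs to be fixed and documented, as
   any monotone variant carries the same class information) — 90 values
   in the full 3 × 5 × 6 configuration; and *wavelet coefficient
   features* (WCF) — the raw coefficients in fixed (channel, band,
   index) order, 27 per single band, optionally thresholded: a
   coefficient is zeroed when its magnitude, normalised by the
   channel-band block's maximum, falls below ε (the wavelet-compression
   rule; a raw-magnitude mode is available behind a flag). Thresholding
   zeroes in place rather than shortening, so the classifier input
   dimension is constant across ε.

4. **Selection and classification.** Features can be ranked by AUC
   computed with the rank-sum formulation, LA as the positive class
   (`auc_rank_features()`), and band/channel/statistic configurations
   compared exhaustively by cross-validated accuracy
   (`combination_search()`), which is the authoritative selector.
   Classification uses a soft-margin RBF-kernel SVM. Hyperparameters
   (C, γ) are grid searched — defaults C ∈ 2⁰…2¹³, γ ∈ 2⁻¹¹…2⁻⁴ — by
   5-fold CV on a seeded stratified 25% subset of the training data,
   ties broken toward smaller C then smaller γ (`tune_svm()`).
   Evaluation is stratified 10-fold CV (`crossvalidate()`; percentages
   averaged over folds, AUC pooled over decision values) or a stricter
   subject-holdout split (`subject_holdout_evaluate()`; 70% of subjects
   train, 30% test, stratified by group, no subject on both sides).
   Features are z-scored with training-side statistics by default:
   RBF kernels on mixed µV²-scale energies and unitless moments are
   scale-pathological otherwise; `scale = FALSE` reproduces the literal
   unscaled protocol. Metrics follow the standard confusion-matrix
   formulas with LA positive; undefined ratios are reported as `NA`
   with a flag, never silently zero.

5. **Discrimination statistics.** Mixture-weighted scatter matrices
   `S_w`, `S_b`, `S_m = S_w + S_b` with the separability criteria
   `J1 = tr(S_m)/tr(S_w)` and `J2 = det(S_m)/det(S_w)`
   (`scatter_criteria()`); a Kruskal–Wallis check on several disjoint
   within-class feature subsamples (`kw_feature_samples()`, 3 per class
   by default giving 6 groups); and a pooled-variance two-sample t-test
   comparing repeated-CV accuracy vectors of two systems
   (`content_effect_ttest()`, Welch behind a flag). When both systems
   sit at the accuracy ceiling the vectors are identical and p = 1 by
   convention, flagged as degenerate.

## What the generator emulates — and what it does not

`simulate_epochs()` builds each trial as background activity plus, on
target trials only, a slow evoked deflection: a half-sine spanning
roughly 0–350 ms post-stimulus whose spectral energy is more than 99%
below 3.75 Hz, with per-trial amplitude jitter (SD 1 µV), latency jitter
(SD 20 ms), and per-channel gains (Fz 0.9, Pz 1.0, Cz 0.8 — largest at
Pz, as for the P300). The group contrast is purely this deflection's
mean amplitude: LA 4 µV vs HA 12 µV by default. These are physiologic
P3 magnitudes, and the contrast is deliberately near the ceiling-accuracy
regime the published system reports; halving the gap lowers accuracy
smoothly, and setting the amplitudes equal removes all class information
(the null-calibration tests rely on this).

The background has two parts:

* stationary `1/f^α` noise (default α = 1, SD 3 µV; α = 0 gives white
  noise for oracle tests), and
* bursty band-limited rhythms in the beta (15–30 Hz) and gamma range
  (30–80 Hz), base SD 3 µV each, whose amplitudes are redrawn
  log-normally (σ = 0.8) on every trial, shared across channels.

The bursts matter for a structural reason. Relative energies are
compositional — the five `Er` values sum to 1 — so any evoked shift of
*total* energy necessarily moves every band's relative energy, and with
a background whose spectrum is identical on every trial, all five bands
become equally discriminative, which no real recording shows. Real EEG
background rhythms wax and wane strongly from trial to trial; modelling
that variability restores the realistic situation in which the
high-frequency bands' energies fluctuate for reasons unrelated to the
class, and only the delta bands carry a usable contrast. Under the
defaults, a single-band search puts A4 clearly first (≈98% accuracy vs
≈90% for the best non-delta band) and A4+D4 with {Er, std} reaches
98–99% in 10-fold CV on ~400 trials.

A seeded fraction of epochs (default 5%) receives an injected ±200 µV
excursion emulating blinks, recorded in a ground-truth log so rejection
can be verified exactly. With the bursty background, rare (< 0.5%)
natural excursions beyond 90 µV also occur and are rejected — as they
would be in practice.

Not emulated: volume conduction/forward modelling, channel covariance
beyond the shared burst amplitude, eye-movement waveform shape, subject-
level amplitude traits (subjects differ only through their trials), and
any dependence of the EEG on the 2D/3D content label. Passing tests
therefore show that the *pipeline* recovers what the generator encodes;
they cannot show that real LA/HA cohorts are separable, and the
published headline numbers (100% CV accuracy, J1 = 11.05,
Kruskal–Wallis p ≈ 0) are data-dependent and not reproducible without
the original recordings.

## Numerical choices and degenerate inputs

* Epoch truncation to 144 samples (above); no padding anywhere, so
  Parseval and perfect reconstruction are exact to 1e−9 and better.
* `Er` is always normalised over all five bands, whichever bands feed
  the classifier, matching the energy-ratio definition.
* Zero-variance bands yield kurtosis/skewness 0 (flagged convention);
  all-zero decompositions make relative energy undefined and raise an
  error rather than returning 0/0.
* Tie-breaks: grid search prefers smaller C then smaller γ; AUC ranking
  breaks discriminability ties by feature name; stratified folds deal
  shuffled class members cyclically, keeping per-fold class proportions
  within one trial of the global ones.
* All randomness flows from explicit seeds fanned out per stage;
  functions restore the caller's RNG state, and a rerun of
  `run_pipeline()` with the same configuration is byte-identical.
* ε = 0 thresholding is the identity; ε = 1 keeps only maximal-magnitude
  coefficients; `zeroed_count` is non-decreasing in ε.

## Problem sizes used in tests

The test-suite cohorts are scaled for a desktop run: recovery and
null-calibration experiments use 5 subjects per group × 135 oddball
trials (≈400 target epochs after rejection), mirroring the published
per-condition trial counts' order of magnitude (≈1000 trials per
condition there); calibration of the statistical tests uses 2000 null
replicates; the Haar oracle runs 100 random length-144 signals. The
same sizes are used by `scripts/acceptance.R`.

## Known limitations

* Trial-level 10-fold CV pools trials across subjects, so within-subject
  correlation can inflate accuracy relative to deployment on unseen
  subjects; both protocols are provided, and the subject-holdout figures
  are the ones to trust for generalisation claims.
* The Haar band labels (Table-style 0–30 Hz) do not coincide with the
  physical dyadic bands at 250 Hz; the package documents the map as a
  labelling layer and leaves `f_top` configurable.
* Only the three midline channels are modelled; no bad-channel
  interpolation (epochs with a flagged channel are dropped entirely).
* The Kruskal–Wallis subsampling harness reproduces the logic of the
  published significance check, not its exact (unavailable) inputs.
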