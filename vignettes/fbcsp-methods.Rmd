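---
title: "Filter-bank CSP valence detection: models, choices, and what the synthetic tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filter-bank CSP valence detection: models, choices, and what the synthetic tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This package implements a complete two-class emotional-valence detection
pipeline for low-density (8-channel) EEG, together with the synthetic-data
machinery needed to validate every stage without access to recorded
subjects. This vignette is the methods account: the models and their
assumptions, the parameters that matter, the numerical choices, and the
limits of what the synthetic experiments demonstrate.

## The pipeline

A session is represented as a continuous `recording()` (channels x samples,
microvolts, 512 Hz, 10/20 labels) plus a `trial_table()` of labeled 5-s
stimulus segments. Processing proceeds:

1. **Broadband preprocessing** — zero-phase 4th-order Butterworth band-pass,
   0.5–48.5 Hz, applied forward–backward (`bandpass()`); the two passes
   square the magnitude response and cancel phase, so band-limited
   transients keep their latencies.
2. **Trial balancing** (`balance_trials()`) — artifact-corrupted trials are
   removed together with one random trial of the opposite class each; with
   no corruption one random trial per class is removed, so every subject
   contributes 12 + 12 trials.
3. **Epoching** (`segment_epochs()`) — 2-s windows with 1-s overlap inside
   each 5-s stimulus segment: 4 epochs per trial, 96 epochs of
   8 x 1024 samples per subject.
4. **Features** — either prior-knowledge asymmetry features or data-driven
   FB-CSP (below).
5. **Classification** — six families (kNN, SVM, LDA, ANN, RF, LR) under
   trial-grouped stratified 12-fold cross-validation, within-subject or
   cross-subject.

## Feature extraction

### A-priori hemispheric asymmetry

`pair_differences()` implements the valence/right-hemisphere prior: the
per-sample difference Fp2 − Fp1 (1024 features per epoch), optionally
extended to the three symmetric pairs (Fp, C, O; 3072 features). Midline
Fz/Cz have no homologue and are excluded. The alpha-band variant is
obtained by composing with the 8–13 Hz zero-phase Butterworth filter; since
both operations are linear they commute, so the order is a non-choice.

`alpha_asymmetry()` computes the classic frontal alpha-asymmetry index
per epoch,

\[ \alpha_{asym} = \ln(\alpha PSD_L) - \ln(\alpha PSD_R), \]

with alpha power integrated over 8–13 Hz from a Welch estimate (1-s Hann
segments, 50% overlap — a standard compromise for 2-s epochs, exposed as
arguments). The index is exactly antisymmetric under a left/right swap and
invariant to common amplitude rescaling.

### Filter-bank CSP

`design_filter_bank()` builds 12 contiguous 4-Hz Chebyshev type II
band-pass filters spanning 0.5–48.5 Hz (order 4 per pass, 30 dB stopband,
stopband edges 1 Hz outside the passband). Two implementation notes:

* The IIR recursions run in compiled code over whole epoch matrices;
  zero-phase behaviour uses odd-symmetric edge extension of length three
  times the filter polynomial length, the standard forward–backward recipe
  for short epochs.
* The lowest band (0.5–4.5 Hz) cannot be realized as a stable
  transfer-function band-pass at 512 Hz — the sub-hertz stopband edge
  pushes poles outside the unit circle. It is therefore realized as an
  order-6 Chebyshev II low-pass with its stopband edge 2 Hz above the band;
  the 0.5 Hz lower edge is already enforced by the broadband preprocessing
  step that the filter bank's input contract assumes. `design_coefs()`
  verifies pole radii and refuses unstable designs.

`fit_csp()` estimates, per band, the class covariances as the per-class
average of trace-normalized per-epoch sample covariances, whitens their
sum, and eigendecomposes the whitened class-1 covariance. The projection
columns simultaneously diagonalize both class covariances; eigenvalues are
sorted decreasing for class 1 (so increasing for class 2, the per-component
pair summing to one). All 8 components per band are retained. The
whitening route is verified in the tests against a brute-force generalized
eigendecomposition to < 1e-6 radians. Spatial patterns (the forward model)
are recovered as the composite covariance times the filters; filter signs
are fixed by making each filter's largest-magnitude entry positive, so
serialized models are reproducible.

`csp_features()` computes, per epoch and band, the variance of each
projected component normalized by the sum over components, then takes the
log: 12 bands x 8 components = 96 features. The log is a deliberate
deviation from a plain variance readout — it conditions the features for
the downstream classifiers — and can be disabled (`log_var = FALSE`). The
normalization makes features exactly invariant to per-epoch amplitude
rescaling; invariance under an arbitrary invertible channel mixing holds up
to the per-epoch trace-normalization weights (exact in the
infinite-epoch limit, a percent-level effect at 24 trials).

Baselines: flattened raw epochs (8192 features), flattened banked epochs
(98304), 95%-explained-variance PCA (`fit_pca()`), and mutual-information
ranking (`mi_rank()`, plug-in estimate over equal-frequency bins) for the
12/24/50/96 operating points.

## Cross-validation protocol

`make_folds()` assigns whole trials to folds — train and test never share
epochs of one trial — stratified so each fold receives an equal share of
each class. Within-subject: 24 trials, 12 folds, 8 test / 88 training
epochs, of which 16 (4 grouped, stratified trials) serve as the ANN
validation set. Cross-subject: all subjects' trials pooled (600 trials,
2400 epochs; 200 test / 2200 training per fold, 200 validation). Every
data-dependent feature stage — CSP projections, PCA, MI ranking, and the
feature standardization — is fitted inside each training fold only;
`cross_validate()`'s prepared context holds exclusively per-epoch
deterministic transforms (filtering, per-epoch covariances), which is what
makes the fold loop affordable and leak-free, and the test suite checks by
hashing that shuffling held-out labels cannot change any fitted stage.

Within-subject aggregation reports the mean of per-subject mean accuracies
with the across-subject standard deviation; cross-subject reports
mean ± SD over folds. Precision, recall and F1 take negative valence as the
class of interest (missing a negative state is the costly error).

The ANN is a single-hidden-layer network trained with minibatch ADAM
(batch 16), cross-entropy with L2 weight decay, at most 1000 epochs and
patience 50 on the validation loss, restoring the best-validation weights.
Weight decay defaults to 1e-3 — sized for roughly 10^2 features against
10^2 training epochs; 1e-4 and below is effectively unregularized at that
ratio and lets the network memorize trial-level noise. kNN is implemented
over explicit distance matrices because the protocol's distance set
(cityblock, chebychev, correlation, cosine, euclidean, hamming, jaccard,
mahalanobis, minkowski, spearman) is not available in any installed
implementation; ties go to the single nearest neighbour. The regularized
discriminant (`gamma` covariance shrinkage toward the scaled identity,
`delta` coefficient thresholding, six discriminant types) is likewise
in-package, cross-checked against `MASS::lda()` at `gamma = delta = 0`.
`grid_search()` discretizes the continuous tuning ranges (5 points,
log-scaled where the range is) and breaks accuracy ties toward the simpler
model.

## The agreement module

`select_polarized()` reproduces the stimulus-selection rule: from a
normative 1–7 valence table, the negative interval is
[min, min + span] and the positive [max − span, max]; with span 1.00 and
the reference table this gives [1.32, 2.32] and [5.28, 6.28], 13 images
per class. `agreement_report()` aggregates per-stimulus self-assessment
(SAM, 1–5) means, rescales them linearly onto the 1–7 scale (the mapping is
an option; `none` is available since the original mapping is not
documented), and reports Bland–Altman bias and 1.96-SD limits of agreement,
Spearman rank correlation (average ranks for ties), and a compatibility
verdict: maximum absolute difference below the mean normative SD.

## The synthetic generator

`generate_dataset()` emulates the experiment's structure so that every
pipeline stage is exercisable end to end: 25 subjects x 26 trials (13 per
class) x 5-s labeled segments at 512 Hz on the 8-channel montage, one
artifact-corrupted trial for 3 subjects (driving the balancing path), a
synthetic normative stimulus pool with polarized selection, and per-subject
SAM ratings tied to the normative scores plus noise. Trials are separated
by 1-s unlabeled gaps; the full 30-s trial protocol (white screen,
countdown, self-assessment) is not reproduced because only the stimulus
segment carries a label.

Ingredients, with the reasoning behind each default:

* **Aperiodic background**: per-channel noise with PSD
  ∝ 1/(knee + f^χ), χ = 1, knee 1 Hz, 10 µV RMS. The knee form is the
  standard aperiodic EEG model; a kneeless 1/f concentrates nearly all
  power below 1 Hz, which broadband-filtered EEG does not show, and makes
  delta-band covariance estimates pathologically low-dof.
* **Electrode gain drift**: per-trial, per-channel lognormal amplitude
  gains (log-SD 0.15) on the background, emulating dry-electrode contact
  fluctuation. This is the class-independent trial-level noise that makes
  the classification problem honest at 22 training trials.
* **Low-frequency artifact residue**: a 0.5–3 Hz source with a random
  spatial direction and lognormal amplitude (15 µV) per trial — the
  ocular/movement residue that survives imperfect cleaning (the package's
  artifact hook is a pass-through by default; cleaning happened externally
  in the workflow this emulates).
* **Planted valence effects** (`default_effects()`): patterned on
  event-related desynchronization/synchronization physiology. Under
  negative valence the alpha-band (8.5–12.5 Hz) variance along a fixed
  unit-norm mixing column rises by a factor 4 while the beta-band
  (20.5–24.5 Hz) variance along the same column falls by the matched
  amount. Each covariance effect is implemented as an *exchange* of
  variance between the planted column and an orthogonal partner, so the
  per-class band power is trace-balanced: with per-epoch trace-normalized
  covariances a single unbalanced source can never reach the closed-form
  top eigenvalue r/(r+1), while the paired construction reproduces it
  exactly at high SNR (0.8 for ratio 4) and removes the trivial
  global-power cue. Because the alpha and beta contrasts are antagonistic
  along the same column, the *broadband* covariance carries (in
  expectation) no class contrast at all: spectral decomposition is
  information-theoretically necessary, which is precisely the claim the
  filter bank exists to exploit. `band_localized_effects()` is this pair
  alone; `default_effects()` adds a right-frontal alpha gain of 1.5 under
  negative valence (right-hemisphere dominance for negative affect; it
  shifts the class-mean asymmetry index by −2 ln 1.5) and a
  non-discriminative posterior alpha rhythm with trial-varying amplitude
  (log-SD 0.5), the dominant ongoing activity any spatial filter has to
  live with.
* Sources are band-limited filtered white noise, not sinusoids, so planted
  effects live at the covariance level — the object CSP actually detects.
* **SAM ratings**: normative score + N(0, 0.4) on the 1–7 scale, clipped,
  mapped linearly to 1–5 and rounded.

Everything is seeded; per-subject streams are independent, so any subject
subset regenerates byte-identically (`dataset_epochs()` exploits this to
generate subjects one at a time and bound memory).

`ground_truth_recovery_report()` attributes fitted CSP structure back to
planted effects: per effect, the class-1 eigenvalue contrast per band is
weighted by the |cosine| between the fitted spatial pattern and the planted
column, and effects claim bands greedily. The pattern weighting matters
when two effects share a mixing column with inverted ratios (the default
antagonistic pair): eigenvalue size alone cannot tell their bands apart.

## Problem sizes in the tests and the acceptance script

The test suite and `scripts/acceptance.R` run the full protocol geometry
(96 epochs x 8 channels x 1024 samples per subject; 2400 pooled epochs for
the fold arithmetic) but scale the expensive statistical checks to sizes
that keep the whole suite in the minutes range on one core: 20 replicates
for covariance-shift recovery, 10 single-subject replicates for the null
calibration (the chance band is computed at the *trial* level — 240 trials
— because the four epochs of a trial are statistically dependent), three
subjects for the within-subject planted-effect classification, and four
subjects for the asymmetry-index analytics. These sizes are the package's
validation design, chosen to give each check a comfortable margin over its
Monte-Carlo error.

## Known limitations

* The synthetic data validates the *pipeline*, not the neuroscience: real
  valence effects are weaker, less stationary and less neatly
  band-localized than the planted ones, and real accuracies on recorded
  subjects will not match synthetic ones.
* No biophysical forward model: mixing columns are abstract unit vectors,
  not dipole projections through a head model.
* ICA is not implemented; artifact rejection is a pluggable trial-level
  hook.
* The EDF reader/writer covers the continuous 16-bit subset with one
  sampling rate across signals — the subset the package itself writes.
* Broadband Butterworth and Chebyshev designs are realized in
  transfer-function form; designs whose poles leave the unit circle are
  refused rather than silently mis-filtered (the lowest filter-bank band is
  a low-pass for exactly this reason).
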