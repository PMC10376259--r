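---
title: "Methods: screening pipelines over facial-feature time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening pipelines over facial-feature time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, the choices made
where the underlying study left the design open, and the limits of what a
green synthetic test establishes. Nothing here states an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The two analysis branches

### Mesh branch

A session is a sequence of 478-landmark face-mesh frames with `(x, y, z, v)`
per landmark. Normalization removes the camera nuisance in two per-frame
linear steps:

1. **Recentring** (`center_frame`): every landmark is translated so a
   designated face-centre landmark sits at the origin. The study says only
   "a landmark in the centre of the face"; we default to index 2, the
   nose-tip vertex of the 478-point topology in 1-based indexing, because
   it is a stable, near-centroid point. The index is exposed everywhere.
2. **Isotropic rescaling** (`rescale_frame`): one scale factor per frame
   maps the largest absolute coordinate to exactly 1, so all coordinates
   lie in [−1, 1] with shape preserved. The target range is stated in the
   source; the granularity is not. We rescale per frame (not per session,
   not per axis): per-axis scaling would distort the face, and per-frame
   scaling additionally removes within-session distance drift.

Dropping `v` gives 478 × 3 = 1434 features per frame. PCA
(`fit_pca`) is fit **on pooled training frames only** — the fit scope is
unstated in the source; pooling one basis across sessions avoids test-set
leakage and makes scores comparable across sessions. Components are the
top-k right singular vectors of the centred frame matrix; each component's
sign is fixed by forcing its largest-magnitude entry nonnegative, so fits
are bit-reproducible. Default k = 16.

The classifier (`train_sequence_classifier`) is a single-layer LSTM,
hidden size 32, reading one frame's features per time step; the final
hidden state feeds a dense softmax head; cross-entropy loss, Adam with
learning rate 0.001 (other Adam constants at the de-facto defaults
β₁ = 0.9, β₂ = 0.999, ε = 1e−8, recorded in code). The parameter layout
uses the two-bias-vectors-per-gate convention, giving the closed form

    n(d, h, c) = 4h(d + h) + 8h + (hc + c)

which is the only common convention that reproduces the published 6466
parameters at d = 16, h = 32, c = 2. The same closed form at h = 1024 for
the 4464-dimensional appearance branch gives 22,487,042 ≈ 22.5 M,
consistent with the published rounding; since no hidden size is printed
for that branch, we treat this as a consistency check, not a target.

Two engineering choices the source is silent on:

- **Input standardization.** Features are standardized per dimension with
  training-set mean/sd (stored in the model, re-applied at prediction).
  PCA scores of normalized meshes can be orders of magnitude below unit
  scale, where a fixed learning rate of 0.001 effectively stalls; this is
  ordinary conditioning, not extra information (statistics come from the
  training set only). Disable with `standardize = FALSE`.
- **Unequal sequence lengths** within a batch are truncated to the batch
  minimum. The generator emits fixed lengths, so this is an edge policy.
- **No early stopping or validation split** — none is described in the
  source; epochs are config.

### AU branch

AU intensity streams (17 channels, FACS 0–5 scale) are segmented into
non-overlapping clips of exactly L frames (512 or 1024; `"all"` keeps the
session whole). The trailing remainder is discarded: the source mentions
neither overlap nor padding, and discard is the simplest policy that can
never leak frames across clips. Each clip is summarized per channel by
temporal mean and variance, concatenated means-first — 2 × |subset|
features. The variance is the population (divide-by-n) estimator by
default; the estimator is unstated in the source and the `variance`
argument accepts `"sample"`.

The printed "significant" channel set {2, 4, 5, 7, 8, 9, 10, 12, 14, 15,
16} includes values (8, 16) that are not OpenFace AU numbers, so the set
cannot be a list of AU ids as printed. `select_au_subset` therefore routes
it through an explicit `index_map`, defaulting to "printed index k = k-th
of the 17 intensity channels" (all printed values are ≤ 17, so the default
mapping is total); any other interpretation can be imposed without code
changes.

Clips are classified with an RBF-kernel SVM. No R SVM implementation is
available in the target environment, so the package ships its own SMO
solver (`src/smo.cpp`, maximal-violating-pair selection, stopping at KKT
gap < 1e−3). It is validated against a frozen scikit-learn `SVC` run on a
fixed dataset (decision values to a few 1e−3, labels exactly) and against
the KKT conditions directly. Hyperparameters are not printed in the
source; defaults are C = 1 and `gamma = "scale"` = 1/(p · Var(X)), both
exposed. Features are standardized per LOSO fold with the training fold's
statistics only.

### Subject-level decisions

LOSO (`loso_clip_predictions`) holds out all clips of one subject per
fold. Each subject's dementia-vote fraction p feeds threshold voting
(`vote`): dementia iff p > t, strict. The source states the rule in both
polarities (dementia-directed with a 25% example; healthy-directed in the
results); we follow the worked example's dementia polarity and expose
`polarity = "healthy"`. Strictness fixes the tie: p = 0.5 at t = 0.5 votes
healthy, and t = 1 can never vote dementia — a documented boundary.

`threshold_sweep` evaluates candidates = sorted unique fractions ∪ {0, 1}
∪ midpoints; every achievable decision pattern occurs at one of these, so
the sweep is exact (verified against a dense 0.01-grid oracle). Reported
operating points:

- **max accuracy**: argmax accuracy, ties toward the smallest threshold;
- **EER**: with finitely many subjects the two error rates rarely cross
  exactly, so the EER point is argmin |FPR − FNR| (same tie-break), and
  the reported EER accuracy is the mean of the two class-wise accuracies
  there (balanced accuracy), which is robust to class imbalance.

The sweep optimizes the threshold on the test predictions themselves —
faithful to the published protocol, and optimistically biased.
`evaluate_au_branch(nested = TRUE)` provides the leakage-free variant
(per-subject threshold chosen on the other subjects' fractions) for
comparison.

## 2. The synthetic cohort generator

The generator states a world with the structure the analysis assumes;
its defaults are the recording conditions of the emulated dataset
(18,000-frame sessions at 30 FPS, 478 landmarks, 17 AU channels,
4464 appearance dimensions, 1–10 sessions per subject, equal class
sizes). Effect sizes are free parameters: the source shows group
differences in AU means and variances only qualitatively, so no value
here is calibrated to the restricted data.

- **AU process**: per channel, a stationary AR(1) signal (lag-1
  correlation 0.95 — facial muscle intensity is smooth at 30 FPS) with
  marginal sd 0.5 around fixed channel means spread over 0.8–2.2, plus
  white noise (`noise_sd`), clipped to [0, 5]. The dementia class shifts
  the mean by `au_mean_shift` and scales the stochastic part's variance by
  `au_var_scale` **before** clipping, so realized moments deviate near the
  scale bounds — the documented consequence of enforcing the FACS range.
- **Mesh process**: a fixed ellipsoidal 478-point template moves along
  three *fixed* smooth anatomical mode fields (deterministic functions of
  the template, shared by every subject and session — facial motion modes
  are shared anatomy; were they redrawn per session, a PCA basis fit on
  training sessions would not transfer to test sessions at all) at
  frequencies 0.3/0.7/1.3 Hz with random per-session phases; the class
  controls the amplitude (`mesh_motion_scale`). Each session then receives
  a random global translation and isotropic scale — exactly the nuisance
  the normalization removes.
- **Appearance process**: a fixed nonnegative base pattern plus noise,
  truncated at 0 (gradient magnitudes are nonnegative), with two separate
  dementia-class offsets: `appearance_signal_strength` on a leading
  subspace (the disease-signal stand-in) and `appearance_bias_strength`
  on every dimension (the institutional-bias stand-in, perfectly
  class-correlated as the worst case).
- **Seeding**: one master seed; per-subject/per-session substreams are
  derived by a keyed integer scheme, so enlarging the cohort never
  perturbs earlier subjects' data, and the caller's RNG state is restored
  after every draw.

What the generator does **not** emulate: AU co-activation anatomy, dropped
or jittered frames, extractor failure modes, non-stationary session
structure (interview phases), correlated noise across landmarks, or any
real covariance between the three streams. A green signal-recovery test
therefore establishes that the pipeline recovers the *configured kind* of
group difference at desk scale without identity leakage — not that the
restricted-data accuracies are reproducible, and not that real dementia
produces effects of this form or size.

## 3. Numerical choices and degenerate inputs

- **Nuisance invariance is exact only when the arithmetic is.** The
  invariance `normalize(T(x)) = normalize(x)` holds bit-for-bit when the
  transform's floating-point arithmetic is exact (e.g. dyadic
  coordinates, integer translation, power-of-two scale — tested as
  `expect_identical`), and to ~1e−15 relative otherwise, because
  `a + s·x` rounds before the normalization can cancel it. Tests assert
  1e−12 for arbitrary real transforms.
- All-zero centred frames reject rescaling (undefined scale); frame-level
  errors propagate with the frame index.
- `fit_pca` requires k < n_frames and k ≤ 1434; explained-variance ratios
  are computed against total column variance, so they are comparable with
  the usual cumulative-variance tables.
- Zero-variance features are given unit scale during standardization
  (both SVM folds and the LSTM) rather than producing NaNs.
- SMO guards the pair curvature at 1e−12 and caps iterations at 1e6; the
  offset uses free support vectors when any exist, else the bound
  midpoint.
- Precision of a never-dementia predictor is reported as 0 with a
  warning; F1 is 0 when P + R = 0.
- `write_au_csv` prints doubles at 17 significant digits so its reader
  round-trips bit-exactly.

## 4. Test-scale parameters

The acceptance suite runs the stated worlds at reduced scale to fit a
single-CPU budget and says so in place: signal recovery and null
calibration use 3,072/2,048-frame sessions and 1–4 sessions per subject
(the clip counts change; the per-clip feature distribution does not);
the bias demonstration uses 64 appearance dimensions; the frame-count
ablation uses 16. Effect sizes follow the stated worlds — AU shift 1.0 on
5 channels for recovery, all-zero effects for the null — and epochs for
the synthetic LSTM runs (40–100) are far below the published 338/110,
which suffices at these scales.

## 5. Known limitations

- The LSTM trains on CPU in R; it is sized for desk-scale synthetic
  cohorts, not for 18,000-frame × hundreds-of-sessions training runs.
- Discrete EER depends on the achievable fraction grid; with few clips
  per subject the EER accuracy is coarse.
- The sweep-on-test operating points inherit the published protocol's
  optimism; use the nested variant for honest point estimates.
- Single-seed determinism holds per platform/BLAS; bitwise equality
  across different BLAS builds is not guaranteed for the LSTM and PCA
  paths.
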