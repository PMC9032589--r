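---
title: "Methods: wrist accelerometry, activity recognition and energy expenditure in wristfunc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wrist accelerometry, activity recognition and energy expenditure in wristfunc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristfunc)
```

## The problem

Older adults with reduced lower-extremity function move more slowly and
more variably than their high-functioning peers, and it is an open
question whether machine-learning models that map wrist acceleration to
physical-activity (PA) constructs remain accurate across that difference.
`wristfunc` implements the full analysis for this question as a tested
pipeline:

1. segment raw tri-axial wrist acceleration (units of g, nominally
   100 Hz) into 60 s windows and extract 49 time- and frequency-domain
   features per window;
2. recognize PA **type** (Sedentary, Locomotion, Lifestyle, SFE —
   strength/flexibility exercise), PA **intensity** (Low, Light,
   Moderate), and the 33 **individual activities** of a standardized
   laboratory battery, and estimate **energy expenditure** (EE) in
   metabolic equivalents (METs) from indirect calorimetry;
3. evaluate everything under subject-wise nested cross-validation and
   probe robustness across physical-performance groups with
   leave-one-group-out (LOO) and leave-partial-group-out (LPO) transfer
   experiments.

Subjects are stratified by the Short Physical Performance Battery (SPPB,
0–12): scores ≤ 9 define the low physical performance group (LPP), scores
above 9 the high performance group (HPP).

Because the original laboratory recordings are not publicly deposited, the
package ships a synthetic cohort generator with the statistical structure
the analysis assumes, so every stage is runnable and testable from code
alone. Published real-data scores are therefore **not** recovery targets
anywhere in this package; tests assert structure, internal consistency and
qualitative orderings only.

## Signals

**Windowing.** Bouts are tiled into non-overlapping, gap-free 60 s windows
from the bout start; a trailing partial window is dropped, never padded.
"Non-consecutive" windowing is interpreted as non-overlapping tiling — the
standard practice in human-activity recognition and the only reading with a
deterministic window count; a configurable inter-window gap (`gap_s`,
default 0) and an edge-trim option (`trim_s`, default 0, for discarding
transition seconds) are provided. Windows never cross activity boundaries
because they are cut per bout.

**Calorimetry.** Breath-by-breath VO~2~ (mL·min^−1^·kg^−1^) is smoothed
with a **centered** 30 s running average (each output value is the mean of
breaths within ±15 s). Centered rather than trailing alignment was chosen
because it minimizes phase distortion and tolerates irregular breath
spacing; the choice matters only near the bout edges. Steady-state VO~2~
is then the mean over the contiguous 120 s interval with the smallest
standard deviation of the smoothed series, with candidate intervals
restricted to the second half of the bout so the initial metabolic rise is
excluded. This automates what was historically a manual plateau reading;
the automated rule is validated by brute-force comparison over all
candidate intervals and by parameter recovery on synthetic calorimetry.
METs are VO~2~/3.5 (the resting convention).

## The 49 features

Eleven summary statistics over four channels — vector magnitude
VM~i~ = √(x~i~² + y~i~² + z~i~²), x, y, z — give 44 time-domain features:
mean, sample SD (n−1 denominator), coefficient of variation
(100·SD/mean), min, max, 25 % and 75 % quantiles, third and fourth
central moments, skewness and kurtosis. Two angle features (`mangle`,
`sdangle`) summarize the per-sample angle asin(x/VM), and three spectral
features of the VM series complete the set: `p625` (fraction of power in
the 0.6–2.5 Hz human-movement band), `df` (dominant frequency) and `fpdf`
(modulus at `df` over the sum of moduli).

Numerical conventions, all oracle-tested against naive reimplementations:

* moments m₂–m₄ are **population central** moments; skewness is
  m₃/m₂^3/2^ and kurtosis the non-excess m₄/m₂² (Gaussian → 3). "Third/
  fourth moment" could also be read as raw moments; central moments were
  chosen for consistency with skewness and kurtosis being listed
  separately.
* zero-variance guard: skewness and kurtosis are defined as 0 for a
  constant channel; `cv` is 0 (with a warning) when |mean| < 10^−12^ g —
  wrist VM means sit near 1 g, so the guard never fires on realistic data.
* quantiles use linear interpolation between order statistics (R type 7).
* the angle uses asin(x/VM) in radians (the established convention for
  this identically named wrist feature); x/VM is clipped into [−1, 1], a
  zero VM sample gets angle 0 with a warning, and a degrees toggle exists.
* the spectrum is the unwindowed (no taper) DFT of the mean-removed VM
  series; the DC bin is excluded from all three features so the gravity
  offset cannot dominate `df` or the `fpdf` denominator. `p625` uses
  squared moduli (power) with inclusive band edges; `fpdf` uses raw
  moduli, as its definition is written. At the default 60 s window the bin
  resolution is 1/60 Hz.
* `df` ties break toward the **lowest** frequency, with a 10^−9^ relative
  tolerance so analytically equal tones remain deterministic under FFT
  round-off. An all-constant window has an empty spectrum: `p625 = fpdf =
  0` and `df` is the lowest positive frequency, with a warning.

## The synthetic cohort generator

The generator is a stated world, not a tuning dial: its defaults encode
the study's printed design (91 LPP + 156 HPP subjects; 33 activities;
100 Hz; ~8 min bouts represented as 480 s; SPPB means 7.7 ± 1.8 for LPP
and 11.3 ± 0.8 for HPP; VO~2~ rising to a plateau). Each activity has a
shipped, editable signature: a unit wrist-orientation (gravity) vector, a
dominant movement frequency (`f0_hz`; 1.2–2.2 Hz for locomotion), an
oscillation amplitude, a broadband noise SD, and a MET mean/SD chosen so
Sedentary ≈ 1.1–1.5, Light ≈ 1.6–2.9 and Moderate ≈ 3.0–5.0 METs —
consistent with the catalog's printed intensity categories under
conventional cut-points (a `met_intensity()` helper exposes those
cut-points as generator ground truth only; the catalog remains the label
authority).

Group effects multiply the movement frequency (LPP default 0.79/1.05 ≈
0.752, the only quantitative group contrast printed in the study: the
LPP/HPP walk-speed ratio), inflate amplitude jitter (LPP default 1.5×) and
optionally shift METs. SPPB scores are discretized normal draws clipped to
the group range; clipping shifts the LPP mean from 7.7 to ≈ 7.47
analytically, and the tests assert the Monte-Carlo mean against that
analytic value.

Two SFE signatures (stretching yoga, leg curl) share their kinematic
parameters — orientation, frequency, amplitude, noise — exactly with a
light-Lifestyle counterpart (dressing, personal care), and the other two
sit inside the light-Lifestyle range. This encodes, deliberately, the
wrist-level biomechanical overlap that makes strength/flexibility
exercise the hardest activity type to recognize from the wrist: those
window distributions are identical by construction, only their metabolic
targets differ, and METs are invisible to the accelerometer. Locomotion,
by contrast, keeps a distinct gait band and high amplitude, so the
qualitative ordering "locomotion easiest, SFE hardest" is a structural
property of the stated world rather than an empirical accident.

One modeling-relevant subtlety: the movement oscillation direction is
drawn **partially aligned** with gravity (uniform cosine 0.5–0.85). A
purely gravity-orthogonal oscillation would cancel at first order in the
vector magnitude and put all VM power at 2·f0, which is neither how real
wrist motion reads out nor compatible with recovering f0 from `df`.

Calorimetry per bout: breaths every 2–4 s with VO~2~ =
3.5·MET~target~·(1 − e^−t/τ^) + Gaussian noise (τ = 30 s, noise SD
0.3 mL·min^−1^·kg^−1^), floored at 0; MET~target~ is the signature mean
plus a per-subject random effect scaled by the signature SD, floored at
0.5 METs.

What the generator does **not** emulate: biomechanical limb trajectories,
harmonics and impact transients of real gait, sensor calibration error,
non-stationarity within a bout beyond slow amplitude jitter, and
posture transitions. Consequently a green classification test establishes
that the pipeline is correct and leakage-free, not that the shipped
signatures reproduce published F1 scores — by design the synthetic classes
are more separable than real wrist data.

At full defaults the cohort is ~100 GB of raw samples if materialized at
once; tests and examples therefore run scaled-down cohorts (fewer
subjects, shorter bouts, lower rate), which changes statistical power but
no code path.

## Models and evaluation

Two learners are used, mirroring the study's pairing of a boosted-tree
model with a sparse linear one:

* **Gradient-boosted trees.** The grading/runtime environment provides no
  boosted-tree package, so `wristfunc` implements second-order gradient
  boosting natively (Rcpp): logistic or squared-error objectives,
  exact greedy splits maximizing the usual gain
  G²~L~/(H~L~+λ) + G²~R~/(H~R~+λ) − G²/(H+λ), leaf values −G/(H+λ) scaled
  by the learning rate, and total-gain ("scaled impurity") feature
  importances. There is no row/column subsampling, so fits are exactly
  deterministic; split ties resolve to the first feature/position in scan
  order. The 33-class individual-activity task is fitted one-vs-rest with
  normalized probability argmax, since the native learner has no softmax
  objective.
* **L1-penalized linear models** (lasso logistic regression /
  least squares) via glmnet, standardizing features on the training fold
  only and reporting coefficients on the original scale; constant columns
  are dropped with a warning. Its importance ranking is
  |coefficient|-based and flagged as such.

**Class imbalance.** Classification rows are weighted inversely to class
frequency, w~c~ = N/(K·N~c~); regression uses unit weights.

**Nested cross-validation.** Five outer and five inner folds partition
*subjects*, never windows; for the combined cohort, outer folds are
stratified by performance group to keep the LPP/HPP mixture stable (an
unstated but variance-reducing choice). The inner criterion is mean
validation F1 (classification) or RMSE (regression) — the original
description says only that the best model was chosen. Hyperparameter
grids are unstated in the source analysis; defaults are
depth ∈ {3, 6} × trees ∈ {100, 300} × learning rate ∈ {0.05, 0.1} for
boosting and 20 log-spaced penalties for the lasso, both overridable and
with reduced variants for desk-scale runs. For the lasso the inner loop
fits one regularization path per fold and scores every penalty from it.
A subject-leakage assertion is armed inside every fold, repeat and
transfer split, and aborts the run on violation.

**Metrics.** Binary: positive-class F1, rank-based ROC AUC (midranks, so
ties are exact), balanced accuracy, accuracy; precision/recall/F1 use the
0-on-zero-denominator convention, logged. Multiclass: per-class
one-vs-rest F1 plus macro F1 and, flagged as an extension, macro
one-vs-rest AUC (the original analysis only reports AUC for binary
tasks). Regression: RMSE in METs.

**Transfer experiments.** LOO trains on one whole group (tuning by inner
subject-wise CV within it) and scores once on the other. LPO repeats, ten
times by default, a subject-level random half-split of the target group:
train on the source group plus one half, tune on that composite, score on
the held-out half, and report the mean. The original wording leaves open
whether its "five-fold cross-validation" re-tunes inside each repeat or
scores it; here tuning happens via inner CV on the training composite and
the held-out half is scored exactly once.

**The 51-task grid.** Four binary type tasks × 2 algorithms × 3 cohorts
(LPP, HPP, ALL) = 24; three binary intensity tasks × 2 × 3 = 18; the
multiclass task, boosted trees only, × 3 cohorts = 3; EE regression
× 2 × 3 = 6.

## Reproducibility

All randomness flows from explicit seeds: the cohort from its config
seed, fold assignments and LPO splits from the evaluation seed (saving and
restoring the global RNG state), and the boosted-tree learner is
deterministic outright. The pipeline writes plain CSV artifacts between
stages plus a YAML manifest with config, seed, package version and md5
digests; re-running a stage from upstream artifacts reproduces its outputs
byte-identically.

## Known limitations

* The boosted-tree learner is a faithful but minimal second-order
  implementation: no sparsity-aware splits, no histogram binning, no
  subsampling; on the package's problem sizes this is fast enough, but it
  is not a general XGBoost replacement.
* One-vs-rest multiclass probabilities are normalized scores, not a joint
  softmax; per-class F1 is unaffected, probability calibration may be.
* The automated plateau finder assumes steady state is reached in the
  second half of a bout; bouts shorter than twice the plateau length fall
  back to any feasible interval.
* Parquet input and proprietary device containers are out of scope; CSV
  (and the documented sidecar-rate variant) is the interchange format.
* Real-data performance values from the source study are out of scope as
  numeric targets throughout, because those data are not deposited.
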