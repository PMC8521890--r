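---
title: "Activity tracking from ear- and waist-level accelerometers: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activity tracking from ear- and waist-level accelerometers: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earmotion)
```

This vignette is the package's account of its science: the measurement
model, the synthetic motion models and their parameters, the feature
definitions and windowing conventions, the classifier, the evaluation
conventions, and the step detector — together with the numerical choices
and the limits of what the synthetic experiments can show.

## Measurement model

A rigidly mounted tri-axial accelerometer measures specific force in the
sensor frame:

$$ a(t) = R(t)^\top \left( a_i(t) + g \right) + e(t), \qquad
   g = (0, 0, 9.81)^\top\, \mathrm{m/s^2}, $$

where $R(t)$ is the body-to-inertial rotation, $a_i$ the kinematic
acceleration in a right-handed inertial frame with $Z$ up, and
$e \sim \mathcal N(0, \sigma_e^2 I)$ isotropic Gaussian noise with the
same SD on every axis. **Sign convention.** Accelerometers measure the
reaction to gravity: a static upright sensor reads $+9.81$ on its up
axis, and $\lVert a \rVert = 9.81$ for any static posture when
$\sigma_e = 0$. The implementation therefore rotates $a_i + g$ (rather
than $a_i - g$) into the body frame; writing the model with $-g$ and a
gravity vector pointing down is the same statement. Orientations are
represented as unit quaternions; interpolated orientations remain
orthonormal to better than $10^{-9}$.

## Synthetic activities

No public recordings exist for the ear/waist setup the package targets,
so the generator defines a minimal motion model per class — rich enough
that the nine classes are separable by the package's own features, simple
enough to be fully auditable:

* **Resting classes** (standing, sitting, lying face-up / face-down / on
  a side) hold a class-characteristic constant orientation plus
  low-amplitude postural sway, modeled as horizontal inertial
  acceleration at the sway frequency. Lying face-up, face-down and on the
  side place gravity on $+x$, $-x$ and $\pm y$ of the body frame;
  sitting differs from standing by a forward pitch that is larger at the
  waist (0.35 rad) than at the ear (0.15 rad) — the physical reason a
  waist sensor separates sitting from standing more easily. Standing
  sway is larger than sitting sway (scale 1.6 vs 0.6), reflecting
  postural control of upright stance.
* **Walking and jogging** superimpose, in the inertial frame, a vertical
  heel-strike pulse train (Hann pulses, width 0.3 of a step period,
  zero-mean) plus a smaller smooth oscillation at the step frequency that
  is phase-locked to the strikes, a fore–aft sinusoid at the step
  frequency, and a lateral sway at half that frequency. Impact
  transients carrying most of the vertical acceleration is what makes
  derivative-based step detection work on real gait, and the phase lock
  keeps the step frequency the dominant spectral line of
  $\lVert a \rVert$.
* **Falling** is a short transient: the orientation slerps from upright
  to a random lying posture along a half-cosine schedule, with an impact
  pulse near the end.
* **Transitioning (TRN)** segments are inserted between any two scripted
  activities; the orientation slerps between the neighboring postures
  with moderate multi-axis jitter.

### Default parameters

| parameter | default | units | rationale |
|---|---|---|---|
| sampling rate `fs` | 100 | Hz | study's device rate |
| noise SD `sigma_e` | 0.05 | m/s² | consumer MEMS noise floor at 100 Hz |
| sway amplitude / frequency | 0.05 / 0.3 | m/s² / Hz | quiet-stance sway magnitudes |
| walking freq / vertical / fore–aft | 1.8 / 2 / 1 | Hz / m/s² / m/s² | typical adult gait |
| jogging freq / vertical / fore–aft | 2.8 / 6 / 2.5 | Hz / m/s² / m/s² | moderate jog |
| fall impact peak / duration | 15 / 3 | m/s² / s | fast transition to lying |
| TRN duration between segments | 1.5 | s | unhurried posture change |
| ear mirror offsets | ±0.08 yaw, ±0.05 roll | rad | left/right ears share head motion but are not identical |

All of these are overridable via `sim_config(params = ...)`.
`make_cohort()` adds per-subject jitter (gait frequency ±0.15–0.25 Hz,
amplitudes ×0.85–1.2, posture and mounting angles within a few degrees)
under deterministic child seeds, so a cohort is reproducible bit for bit
from one root seed.

**Session length.** The emulated protocol visits all eight scripted
activities once; the default script uses 10 s per resting class, 15 s of
walking and jogging, a 3 s fall and 1.5 s transitions (≈ 93 s and ≈ 28 k
samples per subject and sensor). The package's experiments favor many
subjects over long sessions because per-sample features at 100 Hz make
even short segments contribute thousands of instances per class;
protocol-length sessions (10–15 min) are a `default_script()` call away.

**What the generator does not emulate:** biomechanically realistic gait
or head kinematics, sensor bias/scale errors, label noise from manual
annotation, within-class intensity variation, or free-living behavior.
Passing tests therefore demonstrate that the pipeline's machinery is
correct and well-calibrated on data following the stated model — not
that the printed real-data accuracies would be reproduced on new
recordings.

## Features

Thirteen metrics, ten of them per axis, give 33 features per sample and
sensor: raw accelerations, tilt angles
$\varphi_k = \arccos(a_k / r)$ with $r = \sqrt{a_x^2 + a_y^2 + a_z^2}$,
AVC, SMA, and windowed mean, SD, RMS, MIN, MAX, median, MAD and skewness
per axis, plus activity counts per second. Conventions, chosen once and
tested against brute-force formula evaluation to $10^{-9}$ relative:

* **Windows.** `M = 1` for AVC and SMA (per-sample values); a centered
  window of `M = 100` samples, `[i − 50, i + 49]`, for the order
  statistics and moments. At the stream edges windows *shrink* by
  default so every sample keeps a row and labels stay aligned
  (`edge_policy = "drop"` is available).
* **Divisors.** SD, RMS and skewness use the population divisor $1/M$,
  exactly as the defining formulas read.
* **MAD** is the median of *absolute* deviations from the window median
  (a literal reading without the absolute value would be ≈ 0 for any
  near-symmetric window and would contradict the metric's name).
* **Skewness** of a zero-variance window is defined as 0 — constant
  windows are legitimate during resting classes.
* **AVC** at the final sample (no forward neighbor) uses the backward
  difference, keeping one value per sample.
* **Tilt** at $r = 0$ is undefined and returned as `NA`, never silently
  zero; rows with missing features are dropped (with a message) at
  training time.
* **Labels** of a window are the center sample's label; windows
  straddling a transition are *not* re-labeled by majority.
* The **median** of an even-length window is the mean of the two central
  order statistics.

`extract_features(stride = k)` evaluates every `k`-th sample. Windows at
the retained samples are unchanged — striding only thins the heavily
overlapping windows, and is used in cohort experiments (stride 10 ⇒
10 feature rows per second of signal).

## Activity counts

The counts measure is proprietary; the package implements the published
reconstruction: convert to g-units, remove DC, resample to 30 Hz
(linear interpolation), apply the fixed published 21-tap band-pass
filter (passband ≈ 0.3–2.5 Hz), decimate to 10 Hz, rectify, zero below
the 0.068 g deadband, clip at 2.13 g, quantize in steps of 2.13/128 g,
and sum per 1 s epoch. DC is removed *before* filtering so a constant
input yields exactly zero counts rather than a decaying startup
transient. All constants sit in `counts_config()`. Bit-exact agreement
with physical devices is not claimed; the chain is validated against an
independent straight-line reimplementation and by its invariants (null
on static input, monotone in amplitude, deadband and saturation bounds).
The single `counts_ps` feature column uses the vector magnitude — which
axis the original Matlab implementation used is not documented, and the
magnitude is the rotation-invariant choice.

## Classification

`train_ensemble()` implements bootstrap aggregation over CART trees
(`rpart`): each tree sees a bootstrap resample of the training rows
(same size, with replacement), trees are grown essentially to full depth
(`minsplit = 2`, `cp = 0`, depth cap 30 — matching the effectively
unconstrained growth implied by reported tree sizes in this literature),
and prediction is by majority vote with **ties broken by the fixed class
order** for determinism. A reported "learning rate" for bagging is not
part of the algorithm and is accepted only as the shrinkage parameter of
the boosting alternate. KNN and LDA alternates are provided for
comparison; none of the harnesses use them.

`split_dataset()` defaults to a **subject-wise** 70/30 split: per-sample
windows overlap heavily, so a sample-wise split would leak information
between train and test and flatter every accuracy. Because the original
study's wording is ambiguous on this point, sample-wise splitting
remains available (`unit = "sample"`). Counts of units assigned to
training are rounded half away from zero (21 subjects → 15 train / 6
test); both sides must contain all nine classes (best-effort redraws,
then an error).

## Evaluation conventions

Confusion matrices are 9×9 with the fixed class order (LFD, LFU,
Falling, Jogging, LS, Sitting, Standing, TRN, Walking). Percentages are
rounded **half away from zero** to 2 decimals, the convention of printed
tables; `C + NC = 100` per class. Classes absent from a test set yield
`NA` (never 0) so summaries are not silently deflated. The package ships
the printed integer counts of three published reference confusion
matrices (two ears; waist; ears + waist) as plain-text fixtures;
re-deriving every printed per-class percentage from the raw counts is
part of the test suite.

`ablation_run()` uses the raw per-sample acceleration triple per sensor
("ACC only") as its baseline — the natural base model a tree can always
fall back on — and adds one named feature group at a time on an identical
seeded split. `sensor_combination_run()` evaluates placement subsets
(33 features per sensor) on identical splits so accuracies are directly
comparable.

## Step detection

Steps are detected from the AVC signal: the magnitude is lightly
low-passed (window `min(smooth_s, 0.05)` s — differencing at 100 Hz
amplifies wideband noise), differenced, smoothed over `smooth_s = 0.15`
s, and peaks above an adaptive threshold (mean + 0.5 SD, with an
absolute floor of 5 m/s³) separated by a 0.25 s refractory period are
counted. The floor rejects quiescent recordings, whose noise-driven AVC
level stays near 2–3 m/s³ even at $\sigma_e = 0.1$ m/s², while gait
bursts reach 15–20 m/s³; the refractory period caps the cadence at
4 steps/s, above any human gait. One detected peak is one foot strike;
cadence counts both feet, the pedometer convention. The detector's
parameter-recovery behavior (±2 % across 1.2–3.0 Hz noise-free, ±5 %
averaged over seeds at $\sigma_e = 0.1$) is asserted in the tests. The
published 95 % / 90 % walking/jogging step accuracies were measured
against a wrist device on the study's own recordings and cannot be
reproduced without them; the package reports the same accuracy metric on
synthetic gait instead.

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` run, by the package's choice,
a 21-subject cohort with the default ≈ 93 s script, feature stride 10,
subject-wise 70/30 split, and 100 bagged trees on the 99-column
three-sensor matrix (≈ 14 k training rows) — about 1–2 minutes on one
CPU; smaller cohorts back the bagging-vs-single-tree and
permutation-null checks. Every stochastic stage takes an explicit
integer seed, and derived child seeds (per subject, per placement) stay
below $2^{31}$; the same seed reproduces recordings, splits, models and
predictions bit for bit. The engineering gates asserted on this
configuration — held-out accuracy ≥ 0.80, bagged accuracy ≥ single-tree
accuracy averaged over 10 seeds, chance-level accuracy after label
permutation — are claims about the pipeline on the synthetic model, not
about any real dataset.

## Known limitations

* The motion models are deliberately minimal; absolute synthetic
  accuracies are optimistic relative to real recordings (the synthetic
  cohort separates classes more cleanly than humans do, with the
  designed exception of falling vs transitioning).
* The counts chain follows one published reconstruction; other devices
  and firmware versions differ in filters and scaling.
* Gyroscope and orientation channels, proprietary device formats, and
  wrist-device comparisons are out of scope.
* The classifier suite covers the configurations the harnesses need;
  it is not a general AutoML layer (no hyperparameter search, no
  cross-validation schedules beyond the seeded split).
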