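---
title: "Methods: activity recognition and localization from wearable sensor streams"
author: "imupipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activity recognition and localization from wearable sensor streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imupipe)
```

## The problem and the model

Smartphone and smartwatch inertial sensors observe body movement as noisy,
multi-channel time series. This package implements a dual-task pipeline:
from the same 15-second stack of sensor windows, one classifier predicts the
wearer's *activity* (sitting, standing, walking, running, ...) from inertial
descriptors, and a second, independently trained classifier predicts the
*location context* (home, office, street, vehicle, ...) from gait, heading
and ambient-audio descriptors. "Parallel" means task-parallel: the two
models share the preprocessing and windowing stages but no weights.

The classifier is a deep neural decision forest (DNDF). A fully connected
rectifier network maps the feature vector to a 128-dimensional embedding
`z`. Each of `T` soft decision trees routes a sample through its internal
nodes with probabilities `d_n = sigmoid(w_n' z + b_n)`; the probability of
reaching a leaf is the product of its path's gate probabilities, and each
leaf holds a softmax class distribution. The prediction is the
reach-probability-weighted average of leaf distributions, averaged over
trees, and every parameter (network, gates, leaves) is trained jointly by
minibatch Adam on the negative log-likelihood. We chose joint SGD over the
alternating leaf/route optimization of the original neural-forest
literature for implementation simplicity; on the desk-scale corpora used
here the loss trace is well behaved (non-increasing on its smoothed trend,
asserted in the tests).

## Preprocessing choices

**Butterworth cutoff.** The denoiser is a second-order zero-phase
(forward-backward) Butterworth low-pass. Its *operation-level* default
cutoff is 0.001 in normalized units (fraction of Nyquist), but note what
that implies: at a 40 Hz inertial rate the passband ends at 0.02 Hz, which
annihilates the entire 0-4 Hz human-movement band (gain at 2 Hz is about
1e-4). Because the cutoff's units are genuinely ambiguous in the source
material, the *pipeline* default is instead a 10 Hz low-pass
(`filter$cutoff_units = "hz"`), which removes sensor noise above the
movement band while leaving gait intact; both modes are exposed in the
configuration. Zero-phase application was chosen so that filtering never
lags step peaks or heading turns; its amplitude response is the squared
single-pass response, which is what the filter tests assert against the
analytic `1/(1 + (tan(pi w/2)/tan(pi wc/2))^4)` form.

**Windowing.** Five-second windows, stacked in threes with stride one
window. Hamming weights are applied to *copies* used by spectral features;
time-domain step and heading extraction consume unweighted samples, because
tapering the window edges would distort peak amplitudes and valley
positions. Windows are non-overlapping; stacks overlap (stride 1) to
maximize training examples. Both are configurable.

## Activity features

Per window, channel and axis we compute six descriptors (18 slots), giving
3 x 3 x 3 x 18 = 486 slots per stack:

* **Maximum Lyapunov exponent** (Rosenstein small-data method): delay
  embedding with the delay at the autocorrelation's first zero crossing
  (capped at 1/20 of the series length so slow signals still embed),
  embedding dimension from the false-nearest-neighbour operation, nearest
  neighbours outside a temporal exclusion window, and the exponent as the
  slope of the initial region of the mean log-divergence curve. The fit
  region ends where the curve comes within 0.25 nats of its saturation
  plateau (at least 4 points). Exactly periodic samplings produce
  zero-distance duplicate pairs; those are excluded from neighbour
  selection, which is what makes the pure-sinusoid exponent come out at 0
  rather than an artefact of log(0).
* **MFCCs**: magnitude spectrum, triangular mel filterbank, log with a 1e-12
  floor, orthonormal DCT-II, summarized by the frame mean. The standard
  25 ms / 10 ms audio framing collapses to one-sample frames at 40 Hz, so
  the activity bank uses 2 s frames / 1 s hop with 16 filters (13
  coefficients kept). Scaling the signal by c > 0 shifts only coefficient 0
  (the log turns gain into an additive constant absorbed by the DC basis) —
  a property the tests assert to 1e-6.
* **Higuchi fractal dimension** with k_max = 10 (ramp = 1, white noise = 2 as
  the calibration points).
* **False-nearest-neighbour embedding dimension**: smallest d <= 10 at which
  the false fraction drops below 1% (rtol = 15, atol = 2 SD); stochastic
  signals never unfold and report the cap.
* **Skewness and excess kurtosis** (population moments; Gaussian = 0).

Degenerate (constant) inputs short-circuit to finite defaults (exponent 0,
dimension 1, moments 0) with a `degenerate` attribute; no NaN/Inf ever
leaves the feature modules.

## Localization features

Steps are peaks of the net magnitude `|a| - mean|a|`. The natural "mean of
the net magnitude" threshold is identically zero after mean subtraction, so
the default threshold is the mean *absolute* net magnitude, with `zero` and
`quantile` modes available. A 0.25 s refractory window (4 steps/s
physiological cap) resolves conflicts toward the larger peak. Note one
consequence of a purely relative threshold: it is amplitude-scale-invariant
(a tested property), and therefore *any* nonzero noise produces some
supra-threshold peaks — a truly zero step count requires a noise-free
stationary signal, which is how the stationarity tests construct their
fixture.

The per-step "length" is a *duration*: the timestamp difference between the
valleys flanking a peak (named `step_interval` to avoid implying meters).
Boundary peaks lacking a valley on one side get `NA` intervals.

Heading combines two estimators. The magnetometer heading tilt-compensates
the field with the roll/pitch rotation and takes `atan2` of the two
horizontal components (the matrix product alone is a 3-vector; the
scalarization is the standard compass reading). The gyroscope heading
converts body rates to Euler-angle rates (roll/pitch taken from the
accelerometer/magnetometer attitude at the same instant), forms the
incremental rotation quaternion of the rate-times-dt angles, composes it
with the running orientation quaternion — applying the increment once;
composing it with a separate half-Omega rate update would double-count the
rotation, which the closed-form yaw-integration oracle (0.1 rad/s for 10 s
must give 1.0 rad) rules out — and re-normalizes every step, which is why
the quaternion norm stays within 1e-9 over 10^4 steps. Yaw is read off the
quaternion as `atan2(G_x, G_y)` rather than the bare ratio `G_x/G_y`, which
diverges at `G_y = 0`. The two headings are fused by the circular mean,
which survives the +/-pi wrap (the arithmetic mean of 350 and 10 degrees
points south); antipodal headings have no mean and fall back to the
gyroscope value, flagged. `atan2` replaces every printed arctangent to
preserve quadrants.

Rotation equivariance — rotating the world field by alpha shifts all three
headings by alpha — holds *exactly* only when the estimated attitude is
exact. Gait forces and sensor noise corrupt the accelerometer attitude by
~0.07 rad in the default walking world, so the 1e-3 equivariance property
is asserted on a noise-free, level-attitude scenario; on noisy worlds the
property holds only to the attitude-error scale.

GPS contributes a coarse availability flag and speed summary only; no
trajectory reconstruction or map matching is attempted.

## Selection and augmentation

RFE's internal ranker is an L2-regularized one-vs-rest linear classifier
(closed-form ridge on standardized features) — deterministic, fast enough
to run hundreds of times in the property tests, and sufficient to recover
planted informative features in >= 95/100 seeded trials. 5% of surviving
features (ceiling) are dropped per iteration, ties toward the higher index;
the default keeps 50% per bank.

The genetic-algorithm augmentation is crossover-only: each original vector
produces ten offspring, each by swapping the middle third (boundaries at
floor(L/3) and L - floor(L/3)) with a freshly drawn partner. Partners are
restricted to the same class by default — offspring inherit the first
parent's label, and cross-class hybridization would inject label noise —
and each generation crosses the *original*, not chained offspring (both
choices configurable). Augmentation runs inside training folds only, after
the split, so offspring never leak into evaluation.

## The synthetic world

The generator states one concrete world per class and leaves it fixed:

* Activities: sitting (tilted device, 0.03 m/s^2 tremor), standing (upright,
  0.7 Hz sway of 0.35 m/s^2), walking (2 Hz cadence, 2 m/s^2 vertical
  bounce plus a 30% forward second harmonic), running (2.8 Hz, 5 m/s^2).
  Cadences sit in the physiological 0-4 Hz band; amplitudes follow the
  ordering seen in waist-worn accelerometry.
* Locations: audio spectra (band-passed/white noise presets below the 400 Hz
  audio Nyquist: 50-120 Hz "home", 150-250 Hz "office", white "street",
  15-60 Hz "vehicle" rumble), GPS availability and nominal speed (1.4 m/s
  afoot, 10 m/s vehicle), and a yaw-rate turn schedule.
* Physics: gravity 9.81 m/s^2; earth field 22 uT horizontal / -42 uT
  vertical (mid-latitude values); turns rotate the magnetic field and the
  gyroscope rates consistently (and gravity under tilt), so the heading
  pipeline sees coherent inputs and its ground truth (net heading change,
  step count) is recoverable — a tested invariant across seeded scenarios.
* All randomness flows from one seed: a master seed draws per-recording
  seeds and +/-10% jitter on cadence, amplitude and noise.

What a green end-to-end test establishes: the stages compose correctly and
the classifiers can exploit the constructed class signatures. What it does
not establish: performance on real, in-the-wild recordings — the generator
does not model device orientation churn, magnetic disturbances, label noise
or the heavy class imbalance of the public datasets; the dataset adapters
exist for that purpose, and published-scale accuracies require those
downloads and multi-hour training runs, which are out of scope here.

## Numerical and scale choices

* Filter edge effects: odd reflection padding plus exact steady-state
  initial conditions, so DC passes to 1e-9 even at extreme cutoffs.
* DNDF initialization: He-scaled Gaussians for rectifier layers, zero leaf
  parameters (exactly uniform leaf distributions untrained); argmax ties
  resolve to the lowest class index; features standardized with train-split
  statistics.
* The model's input width is taken from the feature layout at run time; the
  published 740-wide configuration is honored when a layout reproduces it,
  but nothing hard-fails on other widths since that composition was never
  itemized.
* The end-to-end check uses 100 recordings of 20 s (two stacks each) and the
  pipeline's default 15-epoch, 128-batch Adam schedule — scaled so the full
  10-fold, two-task run fits a single-CPU desk budget; the corpus is
  crossed (activities x locations round-robin) so neither task can lean on
  the other's signal.
* 10-fold CV is stratified by class; whether folds should be
  subject-disjoint is left to the caller (the synthetic corpus has no
  subject structure).

## Known limitations

* The chaotic descriptors are estimated on 200-sample windows; they are
  stable features in the pattern-recognition sense, not precise dynamical
  invariants at that length.
* The gyroscope heading drifts without an absolute reference; fusion with
  the magnetometer bounds it only as long as the field is clean.
* The step detector reports cadence peaks, not validated footfalls; swing
  artifacts at non-gait frequencies can alias into counts.
* No dynamic window sizing, no SVM localization variant, no mutation or
  fitness selection in the augmentation operator — crossover only.
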