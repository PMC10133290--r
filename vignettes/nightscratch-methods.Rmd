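---
title: "Measuring nocturnal scratch from wrist-worn actigraphy: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring nocturnal scratch from wrist-worn actigraphy: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Nocturnal scratching is a major driver of impaired sleep in atopic
dermatitis, and patient-reported instruments capture it only indirectly.
`nightscratch` implements an objective assessment built from two wrist-worn
6-axis inertial sensors: signal conditioning, a threshold-based hand-movement
filter, non-wear and sleep-window detection, an interpretable + topological +
learned feature bank over 3-s windows, an ensembled binary scratch
classifier evaluated leave-one-subject-out, and per-night digital endpoints
(scratch duration in s/h and scratch intensity in Hz) with the agreement
statistics used to validate them. Because raw patient recordings of this
kind are not publicly distributable, the package ships a seeded synthetic
night simulator that exercises every stage end to end.

## The processing model

**Units and conventions.** Acceleration is in g, angular rate in deg/s at
ingest (converted to rad/s internally), temperature in Celsius. Intervals
are half-open `[start, end)` in seconds relative to the start of a night's
recording; annotations are stored at millisecond resolution.

**Calibration.** Gain and offset per axis are estimated from stationary
epochs by iterative least squares so that stationary acceleration vectors
land on the unit sphere (`autocalibrate()`). The decomposition into gain
and offset is only well determined when the stationary epochs span many
distinct orientations; with two orientations the applied correction still
normalises the norm but individual parameters trade off against each other.
Recovery to within 0.01 of an injected distortion is achieved with roughly
ten postures spread over a night; with a single orientation the function
returns identity parameters and warns.

**Resampling and gravity removal.** All detection runs at 20 Hz (linear
interpolation from the native 50 Hz). Gravity is removed one of two ways:

* accelerometer-only: first-order Butterworth high-pass at 0.25 Hz. All
  filtering in the package is zero-phase (forward-backward with mirror
  padding) so event timing stays aligned with millisecond labels; the
  quoted -3 dB point at the cutoff refers to the single-pass response, the
  zero-phase gain there is -6 dB.
* gyroscope-fused: the orientation quaternion integrates
  `dq/dt = q (0, omega)/2` with an exact per-step axis-angle update and unit
  renormalisation, and in stationary samples the estimate is rotated toward
  the accelerometer's gravity direction by a fraction `alpha = 0.02` per
  sample (a complementary filter). The constants are package choices; they
  give bias-drift suppression without distorting motion segments, and the
  integrator is exact for constant rates, which the tests verify against
  the closed-form solution.

**Movement filter.** Following the deployed two-statistic rule, the vector
magnitude at 20 Hz is low-passed (6th-order Butterworth, 3 Hz) and
high-passed (1st-order, 0.25 Hz), and each second is flagged as movement iff
strictly more than half of its 20 sliding-window CoV values exceed
`theta_cov = 0.41` **and** the maximum per-axis SD of the band-passed axes
in that second exceeds `theta_sd = 0.013` g. Which filtered series feeds the CoV is a genuine
design choice: "remove noise and constant" fixes the filters but not the
statistic's operand. We compute CoV as rolling SD over rolling |mean| of
the *band-passed* VM: with the constant removed the denominator is near
zero and the statistic behaves as a scale-free burst detector, so the
amplitude criterion is carried almost entirely by the per-axis SD threshold.
The alternative reading (CoV of the low-pass-only VM, mean retained) was
rejected because a 0.5 g oscillatory bout then yields CoV around 0.25 and
could never cross the deployed 0.41 threshold — the statistic would be
inert at its own operating point. `fit_movement_thresholds()` reproduces
the quantile-based threshold choice (8% by default) on new data.

**Non-wear and TSO.** A non-movement stretch whose temperature stays below
25 C for more than 10 contiguous minutes is non-wear. The simulator's
worn temperature sits near 32 C and decays toward 22 C with a 3-minute time
constant when the device is removed, so detected non-wear onsets lag true
removal by the ~2.5 minutes the cooling takes — visible in the round-trip
tests. The sleep-opportunity window uses the z-angle heuristic (5-s epoch
means, 5-min rolling median, sustained bouts with successive changes under
5 degrees for at least 30 min) gated to 18:00-12:00 clock time, and hands
are combined by union when their windows overlap: intending to sleep is a
subject-level state, so a quiet wrist should not truncate it. Discordant
windows fall back to the longer one with a warning; a single worn wrist is
used alone.

**Windows and labels.** Training windows are 3 s with 1.5-s overlap, kept
when at least 1 s lies in detected movement (edge windows included), and
labeled scratch iff strictly more than 1 s is annotated scratch on the same
hand. Deployment tiles non-overlapping 3-s windows from the TSO start with
the same >= 1-s movement rule, after excising non-wear.

## The feature bank

Each window contributes, per sensor, 12 channels: the three axes, the
projections on the two leading principal axes of the window covariance
(PC1, PC2), the vector magnitude, and first derivatives of all six (central
differences, one-sided at edges). Eigenvector sign is fixed by making the
largest-magnitude *sample of the projected series* positive: a loading-based
convention would depend on the sensor basis and break rotation invariance,
which the test suite enforces at 1e-8 across random rotations for all VM-
and PC-derived features.

Per channel there are 16 time/frequency descriptors (moments, range
statistics, zero-crossing rate, lag-1 autocorrelation, and Hann-windowed
spectral features with the dominant frequency searched in (0, 10] Hz) and
11 topological features, i.e. 27 values; with 14 cross-channel features
(pairwise correlations, explained-variance ratios, signal-magnitude area,
tilt-angle moments) each sensor supplies 12 x 27 + 14 = 338 interpretable
columns — 338 accelerometer-only, 676 with the gyroscope. The catalog is
frozen and versioned; the totals and the 11-feature topological block are
fixed contracts, while the specific 16 descriptors and 14 cross-channel
features are package choices constructed to meet them.

**Topological features.** The 0-dimensional sublevel-set persistence
diagram of a 1-D window is computed by a union-find sweep (components born
at local minima with plateaus merged, elder rule at merges, essential class
closed at the global maximum). Ten persistence statistics summarise the
lifespans and midlifes (mean, SD, skewness, kurtosis, Shannon entropy of the
normalised set; midlifes are shifted non-negative before normalising), and
the eleventh feature is the L2 norm of the Gaussian persistence curve
`G(t) = sum_i l_i N(t; m_i, 0.5 l_i)` on a 256-point grid spanning the
diagram's range extended by three kernel scales. The implementation is
tested for exact agreement against an independent level-sweep oracle on
1000 random series, and for the closed-series identity that finite
lifespans sum to half the total variation.

**Learned features.** Two small networks are trained on the labeled
windows as binary classifiers and then truncated at their 5-unit
penultimate layer: a two-block 1-D CNN (conv-batchnorm-relu-maxpool twice,
kernel 5, widths 16 and 32) and a bidirectional tanh recurrent network
(hidden size 32), both ending in a dense (16, 5, 1) head. They are written
in plain R with manual backpropagation and Adam; the recurrent unit is a
classical RNN rather than a gated cell, a deliberately modest architecture
for windows only 60 samples long. Their ten penultimate activations extend
the matrix to 348 (accelerometer) or 686 (both sensors) columns.

## Classifier, selection and evaluation

A gradient-boosted tree ensemble (xgboost) sits on top of the combined
features. Within each training set, windows are split 8-2 at random; the
20% validation split drives early stopping and a small grid over tree depth
and `scale_pos_weight` (1 or the inverse class ratio — the weight balances
training only; evaluation always keeps the held-out prevalence). Recursive
feature elimination drops the lowest-gain features stepwise, recording the
validation AUC per size (the elbow curve); the deployed sizes are 16
features for the accelerometer model and 18 with the gyroscope.
Leave-one-subject-out evaluation retrains everything inside each fold —
extractors, feature selection, early stopping — so the held-out subject's
windows touch nothing, which the fold bookkeeping asserts.

## Endpoints and agreement

Deployment pools both hands onto a common 3-s tiling (a tile is scratch if
either hand calls it). Total scratch duration is 3 s per positive tile;
hourly scratch duration divides by the worn TSO hours; scratch intensity is
the mean dominant frequency of positive windows. The dominant frequency is
taken from the *gravity-retained* vector magnitude: with gravity present
the oscillation enters the norm linearly (`VM ~ 1 + a_par sin`), whereas
the norm of gravity-removed linear acceleration rectifies the waveform and
reports twice the true frequency. Agreement statistics are Bland-Altman
mean difference with 1.96-SD limits, Pearson and Spearman correlations
against reference measures and patient-reported outcomes (subject-level
for once-per-study severity scores, night-level for nightly sleep-scale
items), and a one-way random-effects single-measure ICC(1,1) — chosen
because repeated nights are exchangeable repeats with no rater structure;
subjects contributing a single night are excluded with a warning.

## The synthetic night simulator

`simulate_night()` generates both wrists at 50 Hz: gravity along a
piecewise-constant orientation path (posture changes rotate it at a
constant body rate, and the gyroscope reports exactly that rate), plus
event-specific linear acceleration, plus Gaussian noise (default SD
0.005 g, a realistic MEMS noise floor). Scratch bouts are
amplitude-modulated sinusoids with a +/-10% slowly wandering frequency
drawn from 2-5 Hz (the band is a modeling choice, exposed in the scenario),
mixed onto one or two axes with a guaranteed gravity-aligned component, and
accompanied by a low-frequency "arm-drag" term (0.3-1.5 Hz at 15-25% of the
bout amplitude) because real scratching moves the hand across the skin
while it oscillates — a purely narrowband bout would be invisible to a
3 Hz low-pass at the upper end of the band. Hand scratches default to
0.3-1.0 g peak amplitude and finger scratches to 0.02-0.08 g; the latter
sit near the movement filter's SD threshold, which reproduces the
qualitative finding that low-amplitude finger scratches are
disproportionately lost before classification. Non-wear freezes the signal
at the current gravity vector with near-zero noise and cools the device.
`simulate_cohort()` draws a per-subject scratch style (frequency, amplitude
range, finger-scratch fraction) held fixed across that subject's nights so
leave-one-subject-out evaluation is meaningful.

What the simulator does *not* emulate: sleep-stage dynamics, real wake/roll
micro-arousals, device clock drift within a night, magnetometer effects, or
the annotation noise of human video review. Passing tests therefore show
the pipeline's internal consistency and recovery behaviour under controlled
conditions; clinical performance can only be established on real patient
recordings with video-annotated ground truth.

## Problem sizes and numerical choices

The bundled study conditions are scaled for a desk run: unit tests use
minutes-long nights and a 4-subject cohort; the recovery suite uses 10
subjects x 3 nights x 0.4 h with 6 scratch bouts/h, bout lengths 15-35 s,
10 non-scratch movement bouts/h, and hand-scratch amplitudes only. The
sleep-window tests use full 8-h nights. Extractors train for 8-10 epochs
(Adam, learning rate 2e-3 conv / 8e-3 recurrent, batch 64); recursive
elimination drops 25-40 features per step at these sizes, trading elbow
resolution for runtime, with `step = 1` available for the classical
schedule. Zero-variance guards: PC projections of a degenerate window are
zeros, skewness/kurtosis of near-constant sets are zero, spectral features
of an empty spectrum are zero, and an empty diagram contributes ten zeros
and a zero curve norm. All randomness flows from explicit seeds, and
rerunning any stage with the same config and seed reproduces its output
bit-for-bit.

## Known limitations

* The movement thresholds 0.41/0.013 are deployed constants appropriate
  for adult wrist data; on synthetic data the CoV criterion is nearly
  always satisfied and the SD criterion dominates, so threshold refitting
  on new data should use `fit_movement_thresholds()`.
* The boosted top layer is xgboost; LightGBM is an equivalent choice for
  this role and its depth/leaf and class-weight controls map directly, but
  tree-growth details differ between the two.
* The recurrent extractor is a bidirectional tanh RNN, not an LSTM; on 3-s
  windows this is adequate, but it is a simplification.
* The heuristic TSO constants (5 degrees, 30 min, 5-min median, night gate
  18:00-12:00) follow the van Hees z-angle sleep-window heuristic; the
  union rule for combining hands is this package's own declared choice.
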