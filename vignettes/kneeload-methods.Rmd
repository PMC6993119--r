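---
title: "Estimating knee joint moments from two wearable IMUs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating knee joint moments from two wearable IMUs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneeload)
```

## The problem

External knee flexion (KFM) and adduction (KAM) moments are the standard
biomechanical surrogates for knee joint loading: KAM tracks compression of
the medial tibiofemoral compartment (the compartment affected in the common
varus-aligned form of knee osteoarthritis), and KFM complements it for
overall and patellofemoral loading. Both are normally obtained by inverse
dynamics from laboratory motion capture and force plates, which confines
load monitoring to the lab. `kneeload` implements a wearable alternative: a
feed-forward neural network that maps the signals of just two leg-worn
inertial measurement units (IMUs; thigh and shank, six channels each) to
stance-phase KFM and KAM time series, trained against inverse-dynamics
reference moments and evaluated with leave-one-subject-out (LOSO)
cross-validation.

The package deliberately treats the reference moments as *given*: inverse
dynamics itself (link-segment model, anthropometric scaling) is out of
scope. What is modeled is the estimator and everything around it -
preprocessing, network training, cross-validation, metrics - plus a
synthetic cohort generator so the whole pipeline can be exercised and
falsified without access to a motion-capture dataset.

## Pipeline

For each trial (one foot contact of one locomotion task):

1. **Filtering.** The 12 raw IMU channels are low-pass filtered at 15 Hz
   with a zero-phase (forward-backward) 4th-order Butterworth filter, the
   conventional smoothing for gait kinetics. Filtering is applied to the
   full stream *before* cropping so filter edge transients fall outside the
   stance phase.
2. **Stance detection.** The stance phase is the longest contiguous run of
   vertical ground reaction force (GRF) samples at or above 20 N. The
   threshold is applied to the *raw* force channel: smoothing the force
   before thresholding would smear the sharp contact edges by tens of
   samples and make the detected window depend on the filter rather than on
   the contact event.
3. **Cropping and synchronization.** IMU and GRF streams share a time
   origin; the stance window found at the GRF rate is mapped to the IMU
   rate by the exact rate ratio (round-half-up at the boundaries). No
   cross-correlation alignment is attempted.
4. **Time normalization.** Cropped series are linearly interpolated onto
   100 points spanning 0-100% of stance. Linear interpolation is the
   simplest method consistent with a fixed-step representation; the first
   and last samples are preserved exactly.
5. **Amplitude normalization.** Reference moments are divided by body mass
   (Nm/kg) and expressed as external moments, flexion and adduction
   positive.

Stacking all trials gives an input matrix with 12 columns (2 locations x 6
channels) and a target matrix with 2 columns (KFM, KAM), 100 rows per
trial.

## The network and its training

The estimator is a 12-100-20-C multilayer perceptron (C = 2 for the
combined model, C = 1 for independent per-output models; hidden sizes are
configurable, and the combined and independent variants share all code -
only the output layer width differs). Hidden layers use tanh, the output
layer is linear. Inputs and targets are mapped to `[-1, 1]` by per-column
training-set min/max; held-out data are scaled with the *training* scalers
and may legitimately fall outside `[-1, 1]`, in which case they pass
through unclipped.

Weights are initialized with the Nguyen-Widrow scheme (hidden row norms
`0.7 n^(1/f)`, biases spread evenly over the active range), and training is
full-batch Levenberg-Marquardt: solve `(J'J + mu I) delta = -J'e`, accept
the step only if the sum of squared errors decreases. The normal equations
are accumulated over row blocks, so the full Jacobian of a
23,400-row dataset is never materialized; the accumulation is contractually
identical to direct assembly (tested to 1e-10).

Several training details are not uniquely determined by the published
description of this estimator family, so the package fixes them explicitly:

* **Scaling.** Min-max scaling to `[-1, 1]` - the conventional default of
  neural-network regression tooling.
* **Damping schedule.** `mu0 = 1e-3`, x10 on rejection, x0.1 on acceptance,
  abort above `1e10` - standard Levenberg-Marquardt practice.
* **"Gradient".** The stopping rules read the gradient as the infinity norm
  of `J'e`: training stops below `1e-6`, after 6 consecutive epochs without
  a new gradient minimum ("patience"), or at 1,000 epochs. There is no
  validation split: stopping is purely gradient-based.
* **Degenerate cases.** Constant input columns are flagged and mapped to 0;
  if no SSE-decreasing step exists below `mu_max` the trainer stops cleanly
  with reason `"mu_max"` (numerical local minimum) rather than erroring.

## Evaluation

LOSO cross-validation trains on all trials of all-but-one participant and
tests on the held-out participant, once per participant. Agreement between
estimated and reference series is summarized per task and output by:

* **Pearson r** over each 100-step series, pooled with **Fisher's z
  transform** (`tanh(mean(atanh(r)))`); correlations of exactly 1 in
  magnitude are clamped at `1 - 1e-12` with a warning. Pooled r values are
  labelled weak (<= 0.35), moderate (<= 0.67), strong (<= 0.90) or
  excellent (> 0.90).
* **RMSE** (Nm/kg) and **relative RMSE** - RMSE divided by the mean of the
  two series' peak-to-peak ranges, as a percentage. The range-based
  normalizer makes tasks with very different moment amplitudes comparable
  and makes the metric invariant to common rescaling and offset.
* **Discrete load metrics**: the stance peak and the impulse (trapezoidal
  area under the moment-stance curve, unit step 1% of stance, so units are
  Nm·%stance/kg - the conventional label "Nm/kg" for this integral is
  dimensionally incomplete and the package documents the fuller unit),
  compared as signed percent differences.

Aggregation order: per trial, then Fisher/arithmetic means within each fold
and task, then mean ± sample (n-1) sd across folds; cross-task "Mean" rows
are arithmetic columnwise means. Two genuinely open choices are exposed as
flags with these defaults:

* `pooling = "trial"`: per-trial metrics pooled per fold (the alternative,
  metrics on the concatenated trials of a fold, is `pooling = "fold"`);
  fold-level summary statistics are consistent with reporting "averages
  from the cross-validation subsets" either way.
* `signed_pdiff = TRUE`: percent differences keep their sign, which
  reproduces the published pattern of positive means with large standard
  deviations; an absolute-value variant is available.

Model comparison (`compare_models()`) reports `independent - combined`
deltas of r, RMSE and rRMSE per task with an arithmetic Mean row.

## The synthetic cohort generator

The generator emulates the *statistical structure* of a two-IMU knee-sleeve
study - 13 participants x 6 locomotion tasks x 3 trials by default - not
its physics. Design:

* **Task templates.** Each task has parametric stance-phase moment shapes
  (sums of Gaussian bumps: two bumps for the walking tasks' double-peaked
  moments, one for running/cutting, with a sign-flipping late-stance tail
  in the KAM of the change-of-direction tasks), normalized to unit peak and
  scaled by published per-task reference peaks (e.g. 0.67 Nm/kg KFM for
  straight walking, 2.52 Nm/kg for the 45° cut). GRF profiles are the
  classic double-hump (walking) or single-hump (running/cutting) shapes
  scaled by body weight. Stance durations are literature-typical values
  for self-selected speed (0.62 s walking down to 0.20 s fast running);
  the protocol publishes no speeds, so these are deliberately generic
  choices, fixed once.
* **The learnable mapping.** The 12 IMU channels are a *fixed, task- and
  participant-independent* linear mixture of six features: the two latent
  normalized moment curves, their stance-phase derivatives, and two gait
  harmonics. This guarantees by construction the property the original
  study found empirically - that the IMU-moment relationship is learnable -
  while keeping a brute-force oracle possible: with no noise the mapping is
  exactly invertible, so a network trained on any subset of participants
  must recover held-out moments essentially perfectly (the
  parameter-recovery test: mean r > 0.99, rRMSE < 2%).
* **Participant variability.** `participant_gain_sd` controls two effects
  drawn per participant: a scalar amplitude gain on the moment curves
  (visible as `peak x gain` in the normalized targets) and a multiplicative
  perturbation of that participant's copy of the mixing matrix, emulating
  sensor-mounting variation. The second effect is what degrades
  leave-one-subject-out accuracy as variability grows: a purely scalar gain
  cannot, because Pearson r is scale-invariant and a shared linear mapping
  plus per-participant scaling is still exactly learnable. Trial-level
  amplitude/duration jitter scales with `participant_gain_sd / 3`, so the
  fully degenerate setting (`participant_gain_sd = 0`, `noise_sd = 0`)
  yields bit-identical clean moment curves across participants and trials.
* **Noise.** `noise_sd` is a relative level: Gaussian noise with sd
  `noise_sd` x each channel's amplitude is added to the IMU channels, a
  scaled-down version to the reference moments, and sub-threshold (< 20 N)
  noise to the swing-phase force. Inside the recorded stance window the
  force is floored at 22 N so the 20 N detector provably recovers the
  window; each trial also carries 0.3 s of low-amplitude swing padding on
  either side so cropping logic is non-trivial.
* **Seeding.** One master seed; per-participant and per-trial sub-seeds are
  derived by counter-based mixing, so the cohort is bit-reproducible and
  independent of generation order.

What the generator does *not* emulate: musculoskeletal dynamics, soft-tissue
artifact, sensor saturation, marker trajectories, or genuinely nonlinear
IMU-moment relationships. Passing parameter-recovery tests therefore shows
the pipeline is *correct* (it recovers a recoverable mapping), not that the
estimator reaches any particular accuracy on real gait data - the published
per-task accuracies shipped in `reference_continuous_accuracy()` and
friends are reproduced only at the level of their cross-task arithmetic
Mean rows, as worked examples of the aggregation arithmetic.

## Numerical choices and problem sizes

* Zero-phase filtering uses odd-symmetric signal extension plus
  steady-state initial conditions, so a constant signal is preserved to
  machine precision and the realized gain matches the analytic squared
  Butterworth magnitude (prewarped frequency axis) to ~1e-6; the
  extension length is `max(3 filter lengths, 6 rate/cutoff)` samples.
* Stance detection breaks ties by run length only (longest run wins); no
  debouncing.
* Time normalization is exactly idempotent on an already-100-step series.
* The test suite and the acceptance script run the LOSO recovery study at
  a reduced scale chosen to keep the full check comfortably inside a
  desktop coffee break: 5 participants x 6 tasks x 3 trials, hidden layers
  16-4, 40 epochs, three participant-variability levels (0, 0.15, 0.3).
  At this scale the noise-free cohort reaches mean r about 0.9997 and
  rRMSE under 1%, and mean r degrades monotonically (about 0.9997, 0.986,
  0.923) across the variability levels. The full-size architecture
  (100-20 hidden, 13 participants, 1,000 epochs) is the package default
  for real use.

## Known limitations

* The estimator is a generic (not participant- or task-specific) model;
  on real data its accuracy is bounded by how much knee-moment information
  two thigh/shank IMUs carry, which the synthetic cohort intentionally
  idealizes.
* The trainer is full-batch Levenberg-Marquardt; it is the method of
  record for this estimator family but scales cubically in parameter
  count, so very large architectures are out of scope.
* `rrmse` is undefined for two constant series, `percent_diff` for a zero
  reference, and Pearson r for a constant series; all three return `NA`
  with a warning and are excluded from aggregation rather than silently
  imputed.
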