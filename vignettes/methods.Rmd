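---
title: "Methods: simulation, signal cleanup, movement features and genotype classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, signal cleanup, movement features and genotype classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pointback)
```

## The task and the analysis model

The vestibular rotation task probes path integration with vestibular
cues only: a blindfolded, ear-plugged participant seated in a rotating
chair is turned through one of nine scripted rotation sequences and then
points a hand-held tablet back at a remembered reference object. The
tablet records accelerometer (m/s²), gyroscope and compass (degrees)
channels during the pointing response. The analysis asks whether
movement features extracted from these streams separate APOE ε3ε4
carriers from ε3ε3 non-carriers, trial by trial — each trial is a
different rotation, so trials are modelled separately rather than
pooled.

All angles follow one convention, fixed package-wide: compass bearings
in degrees on [0°, 360°), clockwise positive viewed from above. The
"correct position" for end error is the recorded reference bearing in
the world (compass) frame: the reference object is fixed and the
compass measures world-frame bearing, so a perfect responder's final
heading equals the reference bearing regardless of the rotation
sequence. Reference coordinates are recorded as x, y, z, but the
response measure is directional; elevation is carried only as an inert
placeholder and never enters any feature.

## What the simulator emulates — and what it does not

No participant-level sensor data are publicly available, so the
generator is a first-class module: it defines the study conditions
under which every downstream claim is tested.

Each synthetic participant carries a latent movement phenotype:

| parameter | unit | ε3ε3 mean | ε3ε4 − ε3ε3 at `effect_size = 1` | between-subject SD |
|---|---|---|---|---|
| `heading_error_sd_deg` | ° | 12 | +8 | 3 |
| `heading_bias_deg` | ° | 0 | 0 | 4 |
| `hesitation_rate` | stops/trial | 0.6 | +0.8 | 0.15 |
| `jerk_scale` | – | 1.0 | +0.25 | 0.2 |
| `tilt_wobble_sd` | ° | 2.0 | 0 | 0.5 |
| `movement_duration_s` | s | 2.0 | 0 | 0.15 |

The group difference is deliberately placed on three axes jointly —
pointing precision, hesitancy, movement roughness — because the
features span all three; each delta is configurable so importance
behaviour can be probed per feature. `effect_size` multiplies all
deltas: 0 gives a null cohort (identical group distributions, the
chance-calibration condition), larger values proportionally stronger
phenotypes. The published study population (32/21) is the default
cohort size. Values are the package's own choices of a plausible
mid-life movement phenotype: a ~12° one-sigma pointing error for
healthy non-carriers, under one hesitation per two-second response, and
a carrier effect large enough to matter at `effect_size` ≳ 1 but far
from separable. Demographics approximate the study's marginals (age
≈ 63 ± 5.7 years; 17/32 vs 6/21 male; five occupation codes drawn
uniformly).

A response trajectory is minimum-jerk in angle from the post-rotation
bearing `wrap(reference − net rotation)` to `reference + ε`, with
ε ~ N(bias, error_sd²); the pointing error is therefore exactly
recoverable as end error downstream. Hesitations are Poisson-many stop
gates (0.35 s of zero angular velocity with 0.1 s smoothstep ramps)
placed in jittered slots; each stop extends the movement by its own
length, so the inserted count follows the configured Poisson mean
exactly and ground truth is stored per stream. Accelerometer channels
combine centripetal (`r·ω²`, x), tangential (`r·α`, y, with r = 0.3 m)
and gravity (+9.81 m/s², z) components plus white roughness noise, all
scaled by `jerk_scale`; gyroscope channels are emitted as per-sample
angular increments in degrees (rate × 0.003 s), which makes the
degree-valued tilt feature literal. Only the gyroscope period is
documented for the original hardware; all channels share the 0.003 s
timebase for simplicity. A 0.2 s rest pad is recorded at both ends of
the response — the still-held device there anchors the gravity
baseline used by hesitation detection.

Two artifacts are injected on demand: with probability `flip_prob` a
stream is emitted in the 180°-flipped device frame, and
`wrap_guaranteed` recentres trajectories on compass north so every
stream contains a wraparound discontinuity.

What the simulator does **not** model: biomechanically faithful
arm/torso dynamics, magnetometer physics, the rotation phase itself
(only the response window is recorded), sub-movement corrections or
overshoot, and sensor dropout. Passing tests therefore demonstrate that
the pipeline recovers the structure this generator encodes — artifact
round trips, feature arithmetic, effect-size recovery, chance
calibration — not that real tablet data would classify at any
particular accuracy.

## Signal cleanup

*Flip correction.* The original analysis corrected streams recorded
with the device held rotated 180°; the detector is not documented, so
the package declares a stream flipped when the median gravity-axis
accelerometer reading has negative sign (a flat-held device reads about
+9.81 m/s²). The correction re-applies the flip transform — modelled
as the 180° rotation about the device's lateral axis, which both
shifts the compass by 180° and inverts the gravity axis, and is its own
inverse — so correction is idempotent and exact to numerical
round-off. The median makes detection robust to any plausible motion
transient.

*Compass unwrapping.* An 80° threshold on sequential compass values is
applied as a single gate with two outcomes: a successive difference
above 80° in magnitude that a ±360° correction brings under the gate
is a wraparound and is corrected; one that stays above the gate is a
glitch, rejected, linearly interpolated and counted
(`n_compass_rejections`). Whether the original code rejected or
unwrapped at this threshold is not knowable from its description; the
wrap-first-reject-fallback order recovers clean wraps exactly (the
±360k offset is accumulated as an exact multiple of 360) and degrades
gracefully on spikes.

*Smoothing.* The 100-point moving average is centred with truncated
edge windows: a causal filter would lag trough locations by half a
window (~0.15 s) and bias hesitation positions. Output length equals
input length; the filter is linear and bounded by the input range.

*Peak detection.* A forward scan commits alternating maxima/minima
each time the smoothed series reverses by more than a prominence floor,
set to 5% of the series' dynamic range (no prominence value is
documented; 5% suppresses residual noise wiggles after 100-point
smoothing while passing any genuine stop). Endpoints are never
extrema, so monotone and flat series yield no events.

## Features

The 27-value layout (1 end error + 1 displacement + 3 tilt + 9 rate of
change + 3 mean acceleration + 9 jerk + 1 hesitations) is fixed by
`feature_names()` so importance reports are stable. Numerical choices
where the feature definitions leave room:

- **Jerk aggregation.** The construction — block sums of raw
  acceleration over 0.1/0.5/1.0 s, successive differences — defines
  the per-pair values but not the final scalar. The default is the mean
  of *absolute* differences scaled by the interval (m/s³): a signed
  mean cancels to ≈ 0 on any back-and-forth movement and would carry
  almost no information. `mode = "signed"` is available.
- **Rate-of-change aggregation** across blocks is the arithmetic mean
  of per-block averages; only the per-block averaging is documented.
- **Hesitation stop threshold.** A trough counts as a stop when the
  smoothed, gravity-removed acceleration magnitude falls below 10% of
  the trace's 95th percentile — the movement must genuinely stop, not
  merely slow. Gravity is removed per axis using the median over the
  0.1 s rest edges of the recording; subtracting a whole-trace median
  instead would leave the one-signed centripetal component in the
  baseline and lift the magnitude floor above the stop threshold.
  Magnitude is the Euclidean norm over the three axes (the axis
  combination feeding peak detection is not documented). Only troughs
  flanked by committed peaks on both sides count, which excludes the
  natural low-speed shoulders at movement onset and end.
- **"Compass points"** in the displacement feature are heading samples
  in degrees (the feature's unit is degrees), not 32-point compass
  sectors; the sum of absolute consecutive differences is taken on the
  unwrapped heading.
- Per-axis features are kept per-axis (the feature table notes axes
  explicitly); an optional pairwise-correlation filter
  (`filter_correlated()`, drop one of any pair with |r| > 0.95) is
  provided but disabled by default, as no threshold is documented.

Degenerate inputs error early and specifically: empty channels, traces
shorter than one block (rate of change) or two blocks (jerk), and
single-sample heading series are rejected rather than silently padded.

## Classification

Per trial, the table is one row per participant: 27 features plus age
(standardised), sex and occupation (one-hot with level sets fixed from
the full table so every fold shares one schema). The positive class for
F1 is ε3ε4, the risk group; the binary reading is the default because
the task is risk detection, and a prevalence-weighted two-class F1 is
available (`f1_average = "weighted"`). The documented chance constant
of 0.57 for this design is not reproducible from the 32/21 split under
any standard convention, so the package always estimates chance
empirically by label permutation (`permutation_null()`).

Stratified five-fold cross-validation deals each class's members across
folds within one of each other (fold sizes 11/11/11/10/10 at 32/21).
Hyperparameters — SVM kernel × C over {0.5, 1, 3, 5, 10, 20}, MLP
weight decay over {0.0001, 0.0005, 0.001, 0.002} — are selected per
outer fold. The published description implies a single grid search
without stating its nesting; the default here nests an inner stratified
3-fold grid search inside each training portion, because an un-nested
search lets selection see test folds and inflates scores. A
`nested = FALSE` mode (selection by training-set resubstitution) is
kept for comparison. Standardisation always uses training-fold
statistics only — a structural test poisons held-out rows with
sentinels and asserts the training-side statistics and selected
hyperparameters are unchanged. All stochastic components (folds, forest
and network initialisation, importance permutations) draw seeds derived
deterministically from one master seed.

The MLP is a single-hidden-layer network (5 units, 200 iterations) with
the decay grid as its regularisation path. Importances: impurity (mean
Gini decrease) for the forest; for SVM and MLP, permutation importance
on held-out folds (5 permutations per feature), since those models have
no native importance. Scores are averaged over folds, clipped at zero
and renormalised to sum to 1; an all-zero vector falls back to uniform
with a warning.

## Problem sizes and tolerances used by the validation suite

Feature/oracle equivalence uses 500 random streams at 10⁻⁹ relative
tolerance; metric checks enumerate every truth/prediction assignment up
to n = 8. Cohort-level checks run the un-nested search over a reduced
grid (C ∈ {1, 5}, α = 0.001, 150 trees): chance calibration compares
each trial of one null cohort against a 30-permutation band; effect
recovery averages the per-trial best F1 over ten seeded cohorts at
effect sizes {0, 0.5, 1, 2}, allowing one inversion, and checks that a
majority of trials exceed F1 = 0.6 at effect size 3. Artifact round
trips are exact to 10⁻⁹ degrees; hesitation recovery requires exact
count agreement on ≥ 90% of 200 default-noise streams. These sizes are
the package's chosen trade-off between Monte-Carlo resolution and a
test suite that runs in minutes.

## Known limitations

- The simulator's phenotype is low-dimensional by design; real
  carrier/non-carrier differences are unlikely to be three clean axes,
  and real compass noise is structured (soft-iron distortion, jitter)
  rather than absent.
- Gyroscope "rate of change" inherits the documented
  sum-divided-by-count construction on per-sample increments; its
  nominal °/s unit is conventional rather than a calibrated angular
  rate.
- With 53 participants a single fold contains 10–11 people, so fold
  metrics are coarse (F1 steps of ~0.1) and per-fold grid selection is
  noisy; conclusions should rest on fold means across seeds, as the
  validation suite does.
- The three-second retention delay and the chair's rotation profile are
  not modelled; nothing in the recorded response window depends on
  them under this generator.
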