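---
title: "Detecting compensatory movements in low back pain exercises: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting compensatory movements in low back pain exercises: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcmdetect)
```

`tcmdetect` classifies sets of three low back pain rehabilitation
exercises — Prone-Rocking, Bird-Dog and Bent-over Rowing — as clinically
prescribed execution (CPE) or typical compensatory movement (TCM) from
three spine-mounted tri-axial accelerometers. This vignette explains the
models implemented, the choices made where the design was genuinely
open, and what the synthetic-data generator does and does not emulate.

## The measurement model

Three accelerometers sit at L5/S1 (sensor 1), the Th1/C7 transition
(sensor 2) and the back of the head (sensor 3), axes roughly aligned
with the body: X cranial→caudal, Y lateral→medial, Z ventral→dorsal.
Signals are sampled at 200 Hz with 12-bit resolution; the package models
the quantizer over a configurable full scale (default ±4 g — the ADC bit
depth fixes the level count, not the range, so the range is a package
choice) with additive Gaussian sensor noise before quantization.

For slow exercises the acceleration is dominated by gravity, so the
tilt of a sensor relative to the gravity vector is recoverable per
sample as

$$\varphi = \arccos\!\left(\frac{A_Z}{\sqrt{A_X^2+A_Y^2+A_Z^2}}\right),$$

in [0°, 180°]. Zero-norm samples have no defined direction; they are
flagged missing and a set is rejected when more than 1% of its samples
are invalid — on real 12-bit data a zero-norm reading is essentially
impossible, so this guards against corrupted files rather than noise.

## Preprocessing

Push-button markers delimit the set start and the end of every
repetition; with 7 markers a set yields 6 repetitions on half-open
sample intervals $[m_i, m_{i+1})$, so boundary samples are never counted
twice. Within a set, the longest repetition defines the reference grid
(100% duration); every repetition is interpolated onto that grid
uniformly in normalized time and the channels are averaged sample-wise.
Linear interpolation is used: the signals are slow relative to 200 Hz,
so higher-order schemes would change nothing above the noise floor.
Averaging in normalized time is required for sample-wise averaging of
repetitions that differ in length; no outlier handling beyond the
averaging itself is applied.

## Features

On each averaged set the pipeline computes, per channel, the root mean
square (aRMS), maximum, variance, skewness and kurtosis, and per sensor
the tilt RMS (φRMS); the signed tilt differences φ₁−φ₂ and φ₂−φ₃ give
max(Δφ₁,₂) and max(Δφ₂,₃). That is 5 × 9 + 2 + 3 = 50 features, or 16
in single-sensor mode (5 × 3 + 1). Conventions worth stating:

* all moments are population moments (divide by N), and kurtosis is raw
  (a normal series gives ≈ 3), matching the defining equations;
* Δφ is the signed difference before the maximum (the subtraction order
  follows the sensor indices);
* a constant series has undefined skewness/kurtosis; both are set to 0
  with a warning so degenerate synthetic inputs keep the matrix
  complete;
* each feature column is z-scored with the population SD over **all**
  rows of the matrix, as the completed feature table is normalized in
  the study protocol. This leaks scaling statistics across any later
  train/test split; `loso_evaluate(..., scaling = "train_only")`
  provides the leakage-free variant, but the default reproduces the
  protocol.

## Feature selection

Wrapper forward selection: starting from the empty subset, every
remaining feature is appended in turn and the subset scored by the
pooled misclassification rate of the CART classifier under
category-stratified, seeded 5-fold cross-validation. The best candidate
is accepted while it strictly improves the loss; the subset is capped at
5 features (the N_Sub ≤ N/2 overfitting guard with N = 36 taken at face
value from the protocol, although 36 is more plausibly the test-fold
size of 180/5 than a training-set size). Open points resolved here:

* the protocol mentions random subsets in passing but describes — and
  its small evaluated-combination counts imply — deterministic greedy
  forward selection, which is what is implemented;
* the empty-model baseline loss is the minority-class proportion (the
  best label-only classifier);
* ties between equal-loss candidates break towards the
  lexicographically smallest feature name, for reproducibility;
* a fold draw that leaves a training split single-class is redrawn with
  the next derived seed (at most 10 attempts).

## The CART classifier

Recursive binary splitting with the Gini index $G = 1 - \sum_k p_k^2$;
candidate thresholds are the midpoints between consecutive distinct
sorted values, rows with value < threshold go left, and prediction at
exactly the threshold goes right. Growth stops at pure nodes, exhausted
features, or when no split strictly reduces the child-count-weighted
impurity; leaves carry the majority class with ties going to CPE
(compensation is only flagged on evidence). The one-use-per-feature rule
is applied globally — each feature appears at most once in the whole
tree, the stricter reading of "use each feature only once"; a per-path
option exists but is off by default.

Split-quality comparisons (between thresholds, between features, and
against the parent) are made in exact integer arithmetic on
cross-multiplied impurity numerators, so knife-edge floating-point ties
cannot make tree growth depend on evaluation order. All counts involved
are far below 2^53, so the products are exact in doubles.

Validation is leave-one-subject-out: every subject's six rows are held
out together, the tree is refit on the remaining subjects and the
held-out rows predicted; confusion counts are pooled and reported as
accuracy, sensitivity and specificity with TCM as the positive class
(the convention is ours; the protocol does not name its positive class).

## The synthetic cohort generator

The original recordings are available only on request, so the package
generates cohorts with the study's structure: per subject, exercise and
category, 3 sets of 6 repetitions; 30 subjects give 180 analysis sets
per exercise. Kinematics are parametric raised-cosine tilt pulses per
repetition — the pipeline consumes accelerations only, so no
biomechanical simulation is needed — projected onto gravity
($A_X = g\sin\varphi$, $A_Y = -g\cos\varphi\sin\rho$,
$A_Z = g\cos\varphi\cos\rho$ with mounting roll ρ), with additive
Gaussian noise and 12-bit quantization. Repetition durations are
log-normal (the protocol states only that speed varies); markers are
placed exactly at repetition boundaries, with a short static lead-in and
tail so every marker falls inside the recording.

Default study conditions (chosen once; the protocol reports no raw
amplitudes or tempi, so these are plausible values, not reported ones):
mean repetition duration 3 s (4 s for the slower Bird-Dog), duration CV
0.15, noise SD 0.25 m/s², g = 9.81 m/s². Between-subject variability:
a shared baseline-lean offset (SD 8°; bent-over postures differ
strongly between individuals), per-sensor mounting pitch (SD 2°) and
roll (SD 8° — the axes are only *roughly* aligned when sensors are
taped to the skin), a log-normal speed factor (CV 0.10) and a
log-normal per-subject noise factor (CV 0.40; attachment quality and
soft tissue vary). The subject offsets are shared between categories,
which is what makes leave-one-subject-out the honest validation scheme
even in simulation.

The TCM signatures mirror the clinically described compensations, and
their parametrisation is deliberately calibrated so that the features
reported as discriminative for each exercise are the generatively
informative ones:

* **Prone-Rocking** — longitudinal twist: lateral (Y) acceleration
  oscillation at sensor 2, amplitude 1.5 m/s², 2 cycles/repetition →
  raises `var_Y2`.
* **Bird-Dog** — head tilt-up with lumbar extension: a downward
  raised-cosine excursion of the head sensor's Z channel (1.2 m/s²,
  1 cycle, in phase with the limb lift — the head tilting away from
  gravity lowers its Z projection) → raises `var_Z3`; plus a 12° tilt
  offset of the lumbar sensor → shifts `phiRMS_1`.
* **Rowing** — rounded lower back by posterior pelvic tilt: an 18° tilt
  offset of the lumbar sensor, which makes its tilt diverge from the
  upper-back sensor → separates `max(Δφ₁,₂)`, in which the shared trunk
  lean cancels; plus a 10° dropped-head tilt offset of sensor 3 →
  shifts the Z3 level and `aRMS_Z3` moderately.

Two design points deserve emphasis because they are easy to get wrong in
simulation. First, effects must change *amplitude*, not waveform
*shape*, unless the real compensation plausibly does: a phase-locked
extra oscillation gives scale-free shape statistics (skewness, kurtosis)
an unrealistically clean class signal. Second, with identical sensor
noise for every subject, the noise *fraction* of a trace becomes a class
signal that kurtosis can read; the per-subject noise factor removes this
artifact. An `effect_scale` argument multiplies all TCM amplitudes:
0 makes the categories generatively identical (the null generator), and
classification accuracy is non-decreasing in it.

Bird-Dog is performed on both sides; the sides are mirror images, which
the generator reproduces by flipping the lateral channels. The default
cohort keeps one pooled Bird-Dog stream so that every exercise
contributes 30 × 2 × 3 = 180 analysis sets; `bird_dog_sides = TRUE`
emulates the full session plan of 24 sets per subject (2 categories × 4
counted exercises × 3 sets). Keeping both sides as analysis rows would
double the Bird-Dog design to 360 sets, which is why the analysis
default uses one stream.

## What the tests show, and what they do not

The test suite checks the pipeline's arithmetic against hand-computed
values and independent loop-based oracles (including exhaustive
enumeration for the tree learner on 500 small seeded datasets, and
`rpart`/`e1071` as external cross-checks), the protocol's exact
combinatorial counts, and three statistical properties of the generator
at study scale (30 subjects, 180 sets per exercise; these sizes match
the emulated study design):

* **null calibration** — with `effect_scale = 0`, LOSO accuracy of a
  tree on the designed discriminator stays inside the two-sided 95%
  binomial band around 0.5 (n = 180) over 20 master seeds. The
  discriminator is fixed rather than re-selected because running
  forward selection on the full matrix and then LOSO inflates null
  accuracy to ≈ 0.54: selection sees the held-out subjects' rows. That
  optimism is a property of the wrapper protocol worth knowing about,
  not a signal in the generator, so the generator-nullity probe
  excludes it;
* **signal recovery** — at `effect_scale = 1`, forward selection
  recovers the designed discriminators (`var_Y2`; one of `var_Z3` /
  `phiRMS_1`; one of `maxdphi_1_2` / `aRMS_Z3`) and LOSO accuracy is at
  least 0.9 (in practice ≥ 0.95 across seeds).

Passing these tests shows the pipeline is a faithful, deterministic
implementation of the method and that it behaves correctly on data with
the study's structure. It does **not** show that the headline accuracies
would be reproduced on the original recordings: the generator's
separations are idealisations, real compensatory movements vary in form
and magnitude, soft-tissue artifact and non-gravitational acceleration
are not modelled, and the marker channel is noise-free by default
(operator-latency jitter is not simulated). The greedy tree learner is
also checked against full tree enumeration only for the bound "greedy
training loss ≥ global optimum": greedy CART is not globally optimal
(an XOR arrangement defeats it), so agreement with an exhaustive search
over all trees cannot and does not hold in general.

## Known limitations

* No automatic repetition detection: segmentation relies on the marker
  channel, as in the emulated protocol.
* Binary classification only; multiple TCM types per exercise are out
  of scope.
* Full-matrix z-scoring (the default, matching the protocol) leaks
  scaling statistics into held-out folds; use
  `scaling = "train_only"` for leakage-free evaluation.
* The single-sensor mode restricts the feature vocabulary but keeps the
  same pipeline; no sensor-fusion or frequency-domain features are
  provided.
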