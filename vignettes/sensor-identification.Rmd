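---
title: "Identifying sensor placement from walking data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying sensor placement from walking data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imusegid)
```

`imusegid` assigns each body-worn inertial sensor to the body segment it is
attached to, using only a few seconds of walking that begin from quiet
standing. This vignette explains the model and its assumptions, the
parameters that matter, the synthetic-data generator that the package is
trained and validated on, and the numerical and design choices made where
the method description leaves room.

## The signal model and its assumptions

An IMU measures specific force `s` (kinematic acceleration minus gravity)
and angular velocity `omega`, both in its own, arbitrarily mounted, sensor
frame. Comparing sensors across segments and subjects requires a common
frame, and the whole method rests on getting there with no magnetometer and
no prior knowledge of mounting:

1. **Inclination from standing.** At rest the accelerometer measures only
   gravity, so the mean static reading determines the sensor's tilt. We use
   the shortest-arc rotation taking that mean onto the vertical; the yaw
   component is unobservable at this stage. Assumption: the recording starts
   with a genuinely static interval of at least ~1 s (the default detector
   accepts a prefix whose gyro magnitude stays below 0.1 rad/s on every
   sensor), and the accelerometer is calibrated well enough that the static
   magnitude lies within ±50% of 9.81 m/s² (hard error otherwise).
2. **Strapdown integration.** During walking the orientation is propagated
   per sample as `R(t+1) = R(t) expm(skew(omega_t)/fs)` — exact for a
   constant rate within a sample, so the constant-rate closed form is
   reproduced to machine precision and no first-order integrator drift is
   introduced. Orientations are re-orthonormalised periodically (every 256
   steps, and at the end) by polar projection. Gyroscope noise and bias
   still accumulate; over the ~5 s horizon used here that drift is small,
   and nothing corrects it (no zero-velocity updates, by design).
3. **Gravity removal and velocity.** `a = R s + (0, 0, -9.81)`; velocity is
   the trapezoidal integral from rest. Velocity drift grows with time, which
   is why the heading uses only the mean velocity of the *first* full
   walking cycle.
4. **Heading alignment.** The signed horizontal angle of that mean velocity
   (a two-argument arctangent; its magnitude equals the arccos of the
   normalised dot product with +x) is removed by a rotation about the
   vertical. Every sensor ends in the gait frame: x along the walking
   direction, y left, z up. Assumption: the subject walks roughly straight
   at a usable speed (mean horizontal speed below 0.1 m/s is a hard error).
5. **Angular acceleration** by central differences (one-sided at the ends);
   unlike translational acceleration it is position-independent on a rigid
   segment, which is what makes the angular features robust to where on a
   segment the sensor sits.

**Per-sensor or common heading?** The static accelerometer observes tilt
only, so each sensor's levelled frame retains an unknown yaw equal to its
mounting yaw. A single trial-wide heading angle can therefore only align
sensors whose mountings happen to share their yaw; with arbitrary mounting
it leaves every sensor in a different frame. The package consequently
estimates and removes the heading *per sensor* (each sensor's own
first-cycle mean velocity — all segments translate with the body, so each
observes the same walking direction), which also makes the whole pipeline
equivariant to any common rotation of the raw data. A `heading_mode =
"common"` (circular-median aggregate) remains available for rigs whose
sensors are mounted with a shared yaw reference.

## Gait cycles

Cycles are detected on the sum over sensors of `||a|| + ||omega||`. Within
one step the acceleration magnitudes and the angular-velocity magnitudes
peak at different phases, so the raw summary is multi-modal; it is smoothed
with a centred moving average (`smooth_s`, default 0.3 s — shorter than a
step, longer than the spacing between the two humps) before peak picking.
Peaks must be at least `min_distance = 0.4` s apart (strides at normal speed
are 1–1.3 s, steps half that) and rise above `median + 0.5 * (p95 - median)`
of the smoothed summary — a height rule that on this near-zero-baseline
signal coincides with a prominence rule and filters the low-amplitude
gait-initiation transients. Peaks are steps; a stride spans two successive
same-foot contacts, so stride boundaries are every second accepted peak.
Whether the first accepted peak is a left or right footfall is irrelevant:
every window spans whole strides either way. Features use the first
`n_cycles` (default 3, allowed 1–3) stride cycles.

## Features and transforms

19 features per kinematic signal (`a`, `omega`, `alpha`) and sensor — RMS
and variance of magnitude/x/y/z, row sums and row maxima of the
between-sensor Pearson correlation matrices per component (autocorrelation
diagonal excluded), and the three inter-axis correlations — 57 in total.
Correlations of a zero-variance series are undefined; they map to 0 with a
warning so the classifier always receives numerics.

Transforms are applied per trial, across that trial's sensors:

* `rank` (default): ascending fractional ranks, ties averaged
  ("1 2.5 2.5 4"). Ranks are invariant to any common monotone rescaling of
  a feature — walking speed, subject size, unit changes — which is exactly
  the variability the method needs to ignore. The cost is metric
  information: only order survives.
* `normalize`: per-trial z-scores. The method description does not pin the
  normalisation down; z-scoring per trial is adopted as the natural
  scale-free choice short of full ranking.
* `raw`: actual values, with the between-sensor correlation families
  dropped — both ranking and those features presuppose a known sensor
  configuration. This "configuration-unknown" mode (33 features) is
  provided behind a flag and is expected to be substantially less reliable.

## Classification

Step 1 classifies each sensor into one of the segment classes (10 for full
body, 5 for lower body plus trunk — left/right not yet distinguished) with
an entropy-based decision tree: binary numeric splits at midpoints between
sorted distinct values, chosen by information gain
(`H = -sum p_i log2 p_i`, gain = parent entropy minus instance-weighted
child entropy). Growth recurses until a node is pure or unsplittable; an
impure node is split even when the best gain is zero, because a zero-gain
split can still enable informative splits below it (mutually dependent
features), and the subsequent pessimistic pruning (confidence factor 0.25,
subtree replacement, minimum 2 instances per side of any split) removes
structure that does not pay for itself. A `criterion = "gainratio"` switch
exists for sensitivity checks. Determinism: among equal-gain candidates the
earliest feature in registry order wins, then the smallest threshold; rows
at a threshold route to the `<=` branch.

Predicted class multiplicities are checked against the configuration (e.g.
exactly 2 feet, 1 pelvis). On violation the assignment is repaired greedily
from the Laplace-smoothed leaf class distributions — most confident sensor
first, into classes with remaining capacity — and always flagged: the
intended workflow treats a flag as "ask the subject to walk again", never as
a silent guess.

Step 2 resolves left vs right upper legs and upper arms against the trunk:
the pelvis (sternum) orientation is obtained by trapezoidal integration of
its gait-frame angular velocity plus linear detrending (the full
differential equation is unnecessary for the small trunk excursions), and
the candidate whose vertical acceleration correlates most positively with
the roll component is the right one. The default is this fixed rule;
`step2 = "tree"` instead trains a tree on the fractionally ranked 45
correlations between the limb's 15 series (accelerations, velocities,
angular velocities, angular accelerations, orientations × x/y/z; integrals
by the same trapezoidal-plus-detrend recipe) and the 3 trunk orientation
axes. Step 3 chains the remaining pairs through already-resolved neighbours
on fixed acceleration components (shoulders↔upper arms z, forearms↔upper
arms x, hands↔forearms y, lower legs↔upper legs x, feet↔lower legs x),
in an order that guarantees each reference is already resolved. Correlation
comparisons closer than 1e-6 are flagged ambiguous; if both candidates of a
pair prefer the same side, the larger margin wins, the other takes the
remaining side, and the result is flagged. The final output is always a
bijection onto the configuration or an explicitly flagged failure.

## The synthetic gait generator

No public recordings accompany the method, so the package ships a simulator
that produces labelled trials with the *statistical structure the
classifier exploits*, rather than biomechanically accurate kinematics:

* Signals are sums of sinusoids at the stride frequency (default 1/1.1 Hz)
  and step frequency (double that), specified per segment class in a frozen
  constants table. Velocities are designed directly and differentiated
  analytically, so integrated velocity recovers the walking direction
  exactly up to boundary effects.
* Left/right anti-phase enters as a half-stride time shift: stride-frequency
  terms flip sign on the left side, step-frequency terms do not.
* Per-class amplitudes were calibrated once so that the acceleration-RMS
  ordering head < sternum < pelvis < shoulder < upper arm < forearm < hand
  < upper leg < lower leg < foot holds with margin across the corpus jitter
  envelope (trial-level amplitude and arm-swing scales 0.9–1.1, bounded
  per-sensor jitter ±3%). The six leg sensors therefore always carry the six
  largest RMS{||a||} values — the premise behind the tree's first split.
* Pelvis and sternum roll at stride frequency with the sign that makes the
  right limb's vertical acceleration correlate positively with the trunk
  roll (the step-2 rule); adjacent same-side segments share
  stride-frequency components on the step-3 chaining axes.
* Each sensor gets an arbitrary mounting rotation (uniform over rotations by
  default; `well_mounted` ~5° misalignments and `aligned` modes exist),
  white noise (defaults 0.02 m/s², 0.002 rad/s — typical MEMS magnitudes),
  and optionally a constant accelerometer bias along a random direction.
  Gyroscope outputs are derived from exact orientation increments, so
  strapdown integration reproduces the simulated orientation to machine
  precision in the noise-free case.
* Gait initiation: the forward-speed ramp spans the first 1.5 strides and
  the oscillation envelope switches on over strides 0.375–1, which keeps
  initiation transients below the peak-acceptance threshold; every detected
  stride boundary then lies in steady-state gait, and ground-truth
  boundaries are defined as the detector's output on the constructed
  noise-free summary.
* `arm_swing_amplitude = 0` reproduces a subject whose arms barely move:
  the arm-related feature separations and the upper-arm left/right margin
  collapse (such subjects are the known failure mode of a walking-based
  identifier).

With the 3 s standing prefix, initiation, and three ~1.1 s strides, a
simulated trial uses roughly 6–8 s of recording — "a few seconds of
walking". (At ~5 km/h three strides alone span ~3.3 s; quoted figures of
about six seconds for such recordings are only consistent with the stride
timing if they include the standing prefix, which is how this package reads
them.)

**What passing on synthetic data does and does not show.** The simulator
makes the ordinal feature structure hold *by construction*, so perfect
accuracy on it validates the machinery — frame recovery under arbitrary
mounting, feature extraction, ranking, tree induction, the left/right
rules — not the empirical claim that real walking produces that structure
with comparable margins. Real recordings add soft-tissue artefact,
within-stride variability, imperfect periodicity, turning, and
subject-specific gait quirks that the generator does not model; published
accuracies on real data (high-90s% for step 1 on a full-body configuration)
are the appropriate external reference and are not reproducible from this
package alone.

## Numerical choices and degenerate inputs

* Gravity constant 9.81 m/s², rest convention: levelled free acceleration is
  zero at rest (`g = (0,0,-9.81)` added after rotation).
* Orthonormality is enforced to better than 1e-9 along every integrated
  orientation series.
* Heading sign: the arccos form alone is unsigned; the y-component of mean
  velocity supplies the sign. Without it, leftward and rightward headings
  are indistinguishable.
* The same analysis window — first cycle for heading, first `n_cycles` for
  features — is defined by detected stride boundaries, so a half-stride
  parity shift in which peak is "first" never changes window lengths.
* Zero-variance correlations → 0 with a warning; zero spread in a
  normalised feature → 0 with a warning; fractional ranking refuses
  non-finite input.
* Serialized models carry a schema version; loading any other version is an
  explicit error. Trees serialize as nested JSON objects, human-auditable by
  design.
* Problem sizes in the test and acceptance suites mirror the study design:
  corpora of 31 trials (527 full-body sensor instances, 248 lower+trunk),
  10-fold stratified cross-validation, 17-trial robustness test sets;
  unit-test fixtures run at 60 Hz with a shortened standing prefix to keep
  them light, acceptance runs at the full 120 Hz defaults.

## Known limitations

* Walking only, from a standing start, roughly straight; no activity
  detection is included (it is assumed upstream).
* No magnetometer, no position tracking, no zero-velocity updates; velocity
  drift beyond the first cycle is deliberately left uncorrected.
* Missing feature values are an error at prediction time (no fractional
  instance weighting); categorical features and multi-way splits are out of
  scope.
* The configuration must be known for ranked/normalized features; the raw
  mode degrades gracefully but substantially.
* Sensors on the same segment, or configurations other than the two
  standard sets, require a `custom` configuration and retraining.
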