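---
title: "Methods: gait analysis from fused INS/GPS streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gait analysis from fused INS/GPS streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gaitkine)
```

## The measurement model

gaitkine consumes the *fused* output of a GPS-aided inertial navigation
system worn on the torso: velocity, acceleration, orientation
(quaternion) and angular rate at 400 Hz in the North-East-Down (NED)
geographic frame. The device's internal error-state Kalman filter is not
re-implemented here — its published output accuracy (velocity ±0.05 m/s,
pitch/roll 0.1° RMS, heading 0.3° RMS) is the package's input contract.

For level walking and running, the anatomical transformation reduces to
four derived channels:

* horizontal speed \(V = \sqrt{v_N^2 + v_E^2}\),
* ground track \(\Psi = \operatorname{atan2}(v_E, v_N)\),
* forward acceleration \(\lVert(a_N, a_E)\rVert\), and
* up-positive vertical velocity/acceleration \(-v_D\), \(a_{up}\).

`atan2` rather than a plain arctangent is deliberate: a heading must
distinguish southbound from northbound motion. Velocity-derived heading
is meaningless near standstill, so below a stall threshold (0.3 m/s,
`compute_ground_track()`) the last valid track is held. Both the
threshold and the hold rule are package choices; heading accuracy of
GPS-aided systems is known to degrade at low speed, and any value in
0.2–0.5 m/s behaves identically on gait data.

## Drift removal and step segmentation

A step is defined kinematically: it begins when the vertical velocity of
the centre of mass crosses zero going downward (the CoM apex) and ends at
the next such crossing; the upward crossing in between marks the lowest
CoM point. This avoids needing touchdown/toe-off detection, and the shift
experiment (below) quantifies exactly how little the per-step metrics
care about that choice.

Vertical velocity carries low-frequency drift (residual accelerometer
bias, inclined terrain), which would bias every crossing. It is removed
by a high-pass FIR designed to a three-parameter specification:
passband edge 0.005 of Nyquist (1 Hz at 400 Hz), stopband attenuation
30 dB, steepness 0.7. The transition band occupies the remaining
\((1-\text{steepness})\) fraction of the interval between DC and the
passband edge (0.3 Hz), and the Kaiser window formulas give the minimum
FIR order meeting that triple (2049 taps at 400 Hz). Two design points
matter:

* **Phase.** Crossing *timing* is the segmentation signal, so the
  symmetric FIR is applied with its group delay compensated, twice
  (forward–backward). The net response is zero-phase; an in-band
  sinusoid's crossings move by less than one sample (asserted in tests).
* **Warm-up.** A zero-phase FIR has a transient of one filter length at
  each end of the record. `segment_gait()` flags steps that start or end
  inside that guard region as irregular instead of reporting them. For a
  2049-tap filter this sacrifices about 5 s at each end of a trial.

Crossings are refined to sub-sample times — the 5 ms timing budget is
finer than the 2.5 ms sample interval — by a least-squares line through
±3 samples around the sign change (falling back to two-point
interpolation if the fitted root leaves the bracketing interval). The
local fit averages sensor noise over seven samples, which matters in slow
walking where the vertical-velocity slope at the crossing is small.
Crossings are amplitude-gated at ±0.02 m/s and same-direction crossings
within 150 ms are merged keeping the steepest; both guards suppress
noise-induced micro-crossings and both values are package choices (the
near-zero threshold is not standardized), sized respectively at ~10× the
in-band velocity noise and below any plausible half-step.

Windows containing motion that is neither walking nor running must be
excluded by the caller; `reject_irregular()` provides a conservative
screen: step duration outside [0.2, 1.5] s, vertical-velocity
peak-to-peak below 0.1 m/s, or duration deviating more than 40% from the
trailing five-step median. These bounds are package inventions (walking
cadences 40–300 steps/min pass; standstill and single-step artifacts do
not) and are deliberately loose — they discard garbage, they do not
adjudicate gait quality.

## Per-step metrics

All integrals are trapezoidal on the sample grid with linearly
interpolated fractional end intervals, so per-step distances telescope
exactly into the whole-trial integral (asserted to 0.1%). Definitions
worth stating:

* *Mean speed* is step length over duration (the time average), not the
  sample mean of speed.
* *Vertical oscillation* integrates the filtered vertical velocity
  (`cumtrapz`) and references it to the mean over a window containing an
  integer number of steps; the per-step *closure residual* (displacement
  change apex-to-apex, zero for periodic level gait) is reported as a
  per-step error estimate.
* *Forward lean* is the mean pitch over the step; the within-step
  statistic is not standardized and the mean is the variance-minimizing
  choice.
* *Body rotation* is the peak-to-peak of yaw *relative to the ground
  track*, unwrapped, so a curved path does not masquerade as trunk
  rotation; it is invariant to constant heading offsets.
* *Contact time* is the duration of the stance whose midpoint falls in
  the step (the pairing rule is a package choice). The duty factor
  expresses it as a percentage of step duration; in walking the stance
  spans more than one step and the value exceeds 100% — this is a
  property of step-referenced normalization, not an error.
* *Flight time/distance* use the window where neither foot is in
  contact; identically zero in walking.

## Sensitivity to the gait-cycle start

`run_shift_experiment()` translates every step boundary by a level
\(\ell \in \{0, \pm5\%, \dots, \pm30\%\}\) of the mean step duration and
recomputes the metrics per step. Because the report summarizes per-step
differences both as means and maxima of absolute and relative values,
either reading ("mean error" or "worst step") is available; the headline
summaries use the mean absolute (relative) difference per level. Time
integrals of periodic signals over a full period are shift-invariant, so
mean speed and step length move by well under a percent; peak-to-peak
metrics are the most sensitive, which the report makes visible.

## Indirect ground contact and GRF estimation

Per-foot ground contact and vertical ground reaction force are estimated
from the six inertial channels (3 accelerations, 3 angular rates) with a
recurrent network. Feature selection in the source experiments showed
these six channels carry the signal; quaternion, speed and vertical
velocity add nothing, so they are not model inputs. Trunk roll at stride
frequency is what disambiguates left from right foot.

The sequence machinery follows standard practice for long 400 Hz
records: windows of 1201 samples overlapping 50%, inputs scaled
per-channel to roughly [−1, 1] (max-absolute scaling, stored with the
model), and a loss masked over the first half of each window so the
network sees context before being scored; stitching takes each window's
second half exactly once, so any sample after the initial warm-up is
predicted by exactly one window.

The layers (GRU and LSTM), backpropagation through time, masked
binary-cross-entropy and masked squared-error losses, Adam, gradient
clipping, variational dropout and early stopping are implemented in the
package in batched matrix form; gradients are verified against numerical
differentiation in the test suite, and training is deterministic under
the model seed. The contact head is a sigmoid (per-foot probability,
binarized at 0.5); the GRF head is a ReLU (force cannot be negative).
The published description fixes layer *types* but not widths or counts;
the package default is GRU(64)–dropout(0.2)–GRU(64), while the
validation studies in this package use a single GRU(32) trained for up
to 30 epochs — on the synthetic benchmark the small model is already
well past the target accuracy, and it keeps a CPU-only training run in
minutes. Contact binarization at probability 0.5 and a 40 ms minimum
stance are package choices (no plausible stance is shorter; the blip
filter removes threshold chatter).

Scoring is range-normalized RMSE in percent. For GRF it is per-sample
over the held-out split; for ground contact time (GCT) the binary
prediction is run-length encoded into stances, matched to reference
stances by maximal overlap (the match fraction is reported, so missed
stances cannot silently inflate the score), and the RMSE of matched
durations is normalized by the reference GCT range. Range normalization
is itself a choice — the alternative (mean normalization) is not
distinguishable from published percentages, but range normalization is
the reading under which body-weight-scale GRF errors land in the
single-digit percent regime.

Training is per-subject by design: indirect GRF estimation is known to
require per-person calibration data, and cross-subject transfer is out
of scope.

## The synthetic gait generator

No public dataset carries this sensor configuration, so validation runs
on `generate_gait()`, which emulates the fused sensor stream and the
instrumented-insole reference *from a known truth* (never the reverse):

* per-step durations with 3% cycle-to-cycle jitter;
* CoM vertical velocity as a per-step sinusoid (walk: 15 mm displacement
  half-amplitude at cadence 120; run: 50 mm at 172);
* speed as a per-step constant plus a within-step oscillation in
  anti-phase with vertical displacement (pendular energy exchange);
* orientation with forward lean, stride-frequency yaw rotation and
  alternating-sign roll; angular rates derived from the quaternion
  derivative, accelerations from the velocity derivative, so all
  channels are mutually consistent;
* stances alternating feet, centred mid-step, lasting a duty-factor
  fraction of the stride (62% walking — double support; 35% running —
  flight), with two-peak (walk) or single-peak (run) vertical GRF
  waveforms scaled so each stance's impulse equals body weight times the
  step period (≈1.03 and ≈2.2 body weights peak respectively);
* insoles sampled at their native 50/100 Hz from the analytic waveform.

The sensor error model injects the published accelerometer budget
(0.04 mg bias, 0.14 mg/√Hz noise density, 0.5% of 16 g full-scale
nonlinearity) into the acceleration channels, orientation noise at the
0.1°/0.3° RMS figures, and a fused-velocity error built as a slow
GPS-correction wander (Ornstein–Uhlenbeck, sd 5 mm/s, correlation time
2 s) plus 1 mm/s white noise, hard-clipped at the ±0.05 m/s bound. The
wander scale deserves a note: ±0.05 m/s is the device's accuracy *bound*,
while the published per-step results (sub-centimetre step length and
displacement errors over ~0.5 s steps) are only achievable if the slow
component of the velocity error is at the cm/s scale in good GPS
conditions; the generator therefore treats the bound as a clip, not a
standard deviation.

What the generator does **not** emulate — and hence what passing tests
do not demonstrate: GPS multipath and outages, soft-tissue/backpack
artifact, asymmetric or pathological gait, slopes beyond a linear drift
term, fatigue-induced parameter drift, and real GRF waveform variety
(only the canonical two-peak/single-peak families are produced).
Accuracy numbers obtained on it are internal-consistency results for the
pipeline under a realistic error budget, not field accuracy claims.

## Problem sizes and numerical choices

The validation studies use 500-step walking and running trials for
segmentation timing and integration-error budgets, a 500-step walk and a
1000-step walk/run mix for the shift experiment, and a 10-minute mixed
trial (8 min training, 2 min held out) for the contact/GRF models —
sizes chosen so the standard deviations and maxima they report are
stable while a complete run stays in the tens of minutes on one CPU
core. Degenerate inputs are handled explicitly: fewer than two apex
crossings yield an empty segmentation with a warning; a constant
reference makes nRMSE an error, not an `NaN`; missing contact data marks
contact metrics absent rather than zero; streams too short for the
filter (about 15 s at the default specification) are rejected with the
required length in the message.

## Known limitations

Step-referenced duty factors exceed 100% in walking (see above); the
irregular-motion screen is heuristic; the CLI stores trained models as
RDS files, which are R-version-portable but not cross-language; LSTM
layers are implemented and tested but the defaults use GRUs throughout;
and the generator's insole noise model (3 N white, clamped at zero) is
simpler than real pressure-insole artifact.
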