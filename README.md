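# gaitkine

Continuous gait analysis from a single body-mounted INS/GPS sensor.

A torso-worn GPS-aided inertial navigation system outputs fused velocity,
acceleration, orientation and angular rate at 400 Hz in the
North-East-Down frame. gaitkine turns that stream into per-step
biomechanics for walking and running on level terrain, for researchers
and practitioners who want lab-grade stride metrics from field
recordings:

* **Anatomical kinematics** — speed `V = √(v_N² + v_E²)`, ground track
  `Ψ = atan2(v_E, v_N)`, forward acceleration, up-positive vertical
  velocity, pitch/yaw from the quaternion.
* **Step segmentation** — a step starts where high-pass-filtered vertical
  velocity crosses zero going negative (the centre-of-mass apex). The
  drift filter is a zero-phase minimum-order FIR (passband edge 0.005 of
  Nyquist = 1 Hz, 30 dB stopband, steepness 0.7); crossings are located
  to sub-sample precision.
* **Per-step metrics** — cadence, step duration/length, mean and
  peak-to-peak speed, vertical oscillation (by cumulative trapezoidal
  integration of vertical velocity) with a per-step closure residual,
  forward lean, body rotation, contact time, duty factor, flight time
  and distance, mechanical energy, rolling distance-window speeds.
* **Shift-robustness experiment** — shifts every gait-cycle boundary by
  ±5…±30% of the mean step duration and quantifies how much each metric
  moves, showing the metrics do not depend on starting the cycle at
  touchdown.
* **Indirect ground contact & GRF** — a recurrent sequence model (GRU or
  LSTM, implemented natively with masked losses over 1201-sample windows
  with 50% overlap) maps the six inertial channels to per-foot contact
  probability and vertical ground reaction force, trained against
  instrumented-insole references; ground contact time (GCT) comes from
  run-length encoding the binarized prediction. Scores are
  range-normalized RMSE (nRMSE, %).
* **Synthetic gait generator** — walking/running/mixed trials with full
  ground truth (apex times, stance intervals, GRF waveforms) and a
  sensor error model (accelerometer bias / noise density / nonlinearity,
  bounded INS/GPS velocity error), so the whole pipeline is testable
  without hardware.

The methods vignette (`vignettes/gait-analysis-methods.Rmd`) documents
the models, parameter choices and limitations.

## Worked example

Simulate two minutes of walking with the default sensor error model,
segment it, and compute per-step metrics:

```r
library(gaitkine)

trial <- generate_gait(gait_scenario("walk", duration = 120, seed = 1))
pipe  <- segment_gait(trial$sensor)          # filter + zero crossings
met   <- step_metrics_table(pipe$anatomical, pipe$v_filtered,
                            pipe$segments, contact = trial$contact,
                            mass = 70)
err   <- segmentation_errors(pipe$segments, trial$truth$steps)

nrow(met)                                    # regular steps analysed
#> [1] 218
round(colMeans(met[c("duration", "cadence", "step_length", "speed_mean",
                     "vertical_p2p", "contact_time")]), 3)
#>     duration      cadence  step_length   speed_mean vertical_p2p contact_time
#>        0.500      120.002        0.699        1.398        0.030        0.621
round(1000 * max(abs(err$start_error)), 2)   # worst apex timing error, ms
#> [1] 2.35
round(1000 * max(abs(met$vertical_closure)), 2)  # worst closure residual, mm
#> [1] 0.86
```

The trial walks at 1.4 m/s with cadence 120, so 0.5 s steps of 0.70 m
and a 30 mm vertical oscillation are recovered exactly; step boundaries
land within ~2 ms of the true apexes and the per-step vertical
integration closes to well under a millimetre despite the injected
sensor errors. (First/last steps inside the filter warm-up are excluded
automatically, hence 218 of 240 steps.)

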