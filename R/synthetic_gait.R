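# Synthetic gait generator.
#
# Emulates the fused 400 Hz INS/GPS output and the instrumented-insole
# force streams for walking and running, with complete ground truth (step
# boundaries, stance intervals, per-step metrics, GRF waveforms). Streams
# are derived from the truth, never the other way round, so every
# downstream stage can be scored exactly.
#
# The gait model: centre-of-mass vertical velocity is a per-step sinusoid
# -A_k sin(2*pi*phi) in the step phase phi (zero, going negative, at each
# apex), horizontal speed is a per-step constant plus a within-step
# braking/propulsion oscillation, trunk orientation oscillates in pitch
# (lean), yaw (rotation about vertical) and roll (side-to-side at stride
# frequency — the cue that separates left from right foot in the inertial
# channels). Stances alternate feet, are centred at mid-step and last a
# duty-factor fraction of the stride; each stance's vertical GRF is a
# standard waveform (two-peak for walking, half-sine-like single peak for
# running) scaled so the stance impulse equals body weight times the step
# period.

#' Accelerometer / navigation error model
#'
#' Defaults follow the sensor-grade error budget of a tactical MEMS
#' accelerometer (in-run bias stability 0.04 mg, noise density
#' 0.14 mg/sqrt(Hz), nonlinearity 0.5% of a 16 g full scale) and a fused
#' INS/GPS velocity error that is bounded (spec ±0.05 m/s) and high-pass
#' in character: a slow GPS-correction wander (Ornstein-Uhlenbeck, sd
#' `vel_wander_sd`, correlation time `vel_wander_tau`) plus a small white
#' component on the 400 Hz fused output. Orientation noise follows the
#' stated 0.1 deg RMS pitch/roll and 0.3 deg RMS heading accuracy.
#'
#' @param accel_bias accelerometer bias, m/s^2 (0.04 mg).
#' @param accel_noise_density m/s^2 per sqrt(Hz) (0.14 mg/sqrt(Hz)).
#' @param accel_nonlinearity fraction of full scale (0.5%).
#' @param accel_full_scale accelerometer full scale, m/s^2 (16 g).
#' @param vel_white_sd white noise on fused velocity, m/s.
#' @param vel_wander_sd sd of the slow velocity wander, m/s.
#' @param vel_wander_tau correlation time of the wander, s.
#' @param vel_bound hard bound on the velocity error, m/s.
#' @param att_noise_deg sd of pitch/roll orientation noise, degrees.
#' @param heading_noise_deg sd of heading noise, degrees.
#' @param gyro_noise_sd white noise on angular rate, rad/s.
#' @param force_noise_sd insole force noise, N.
#' @return list of class `gait_error_model`.
#' @export
error_model <- function(accel_bias = 0.04e-3 * 9.81,
                        accel_noise_density = 0.14e-3 * 9.81,
                        accel_nonlinearity = 0.005,
                        accel_full_scale = 16 * 9.81,
                        vel_white_sd = 0.001,
                        vel_wander_sd = 0.005,
                        vel_wander_tau = 2,
                        vel_bound = 0.05,
                        att_noise_deg = 0.1,
                        heading_noise_deg = 0.3,
                        gyro_noise_sd = 0.002,
                        force_noise_sd = 3) {
  structure(as.list(environment()), class = "gait_error_model")
}

#' Gait scenario description
#'
#' Mode defaults: walking at cadence 120 steps/min, 1.4 m/s, 15 mm
#' vertical half-amplitude, duty factor 62% of the stride (double
#' support); running at cadence 172, 4 m/s, 50 mm, duty factor 35%
#' (flight phases). `mode = "mixed"` alternates walk and run blocks of
#' `block_seconds`. Per-step parameters are constant within a step, so
#' ground-truth step length, mean speed and oscillation amplitudes are
#' exact.
#'
#' @param mode `"walk"`, `"run"` or `"mixed"`.
#' @param duration trial duration, seconds (ignored when `n_steps` set).
#' @param n_steps exact number of steps to generate (optional).
#' @param cadence steps/min (scalar; default by mode).
#' @param speed mean horizontal speed, m/s (default by mode).
#' @param vertical_amp vertical displacement half-amplitude, m.
#' @param duty_factor per-foot stance duration as % of the stride (two
#'   steps): >50 gives double support, <50 gives flight.
#' @param speed_osc within-step speed oscillation amplitude, m/s.
#' @param lean_deg mean forward lean, degrees.
#' @param lean_osc_deg within-step lean oscillation amplitude, degrees.
#' @param rotation_deg body-rotation (yaw about vertical) half-amplitude,
#'   degrees, at stride frequency.
#' @param roll_deg trunk roll half-amplitude, degrees, at stride
#'   frequency (alternates sign with the stance foot).
#' @param heading initial ground track, radians.
#' @param heading_rate slow heading drift, rad/s.
#' @param incline_drift vertical-velocity drift slope, (m/s)/s (terrain
#'   slope / residual bias seen by the segmentation filter).
#' @param jitter sd of cycle-to-cycle step-duration variation (fraction).
#' @param mass subject mass, kg.
#' @param rate sensor output rate, Hz.
#' @param insole_rate insole output rate, 50 or 100 Hz.
#' @param block_seconds block length for `mode = "mixed"`, seconds.
#' @param grf_dip two-peak walking GRF shape parameter (relative third
#'   harmonic).
#' @param errors a [error_model()] or `NULL` for clean streams.
#' @param sync_jump_at optional time (s) of a synchronization jump spike
#'   injected into both vertical acceleration and insole force.
#' @param seed RNG seed for the scenario.
#' @return list of class `gait_scenario`.
#' @export
gait_scenario <- function(mode = c("walk", "run", "mixed"), duration = 60,
                          n_steps = NULL, cadence = NULL, speed = NULL,
                          vertical_amp = NULL, duty_factor = NULL,
                          speed_osc = NULL, lean_deg = NULL,
                          lean_osc_deg = 1, rotation_deg = NULL,
                          roll_deg = NULL, heading = 0, heading_rate = 0,
                          incline_drift = 0, jitter = 0.03, mass = 70,
                          rate = 400, insole_rate = 100, block_seconds = 60,
                          grf_dip = 0.25, errors = error_model(),
                          sync_jump_at = NULL, seed = 1) {
  mode <- match.arg(mode)
  if (!insole_rate %in% c(50, 100))
    stop("insole_rate must be 50 or 100 Hz", call. = FALSE)
  defaults <- list(
    walk = list(cadence = 120, speed = 1.4, vertical_amp = 0.015,
                duty_factor = 62, speed_osc = 0.08, lean_deg = 4,
                rotation_deg = 4, roll_deg = 3),
    run = list(cadence = 172, speed = 4, vertical_amp = 0.05,
               duty_factor = 35, speed_osc = 0.35, lean_deg = 6,
               rotation_deg = 6, roll_deg = 5))
  sc <- as.list(environment())
  sc$defaults <- defaults
  if (mode %in% c("walk", "run")) {
    for (p in names(defaults$walk))
      if (is.null(sc[[p]])) sc[[p]] <- defaults[[mode]][[p]]
    if (mode == "run" && sc$duty_factor >= 50)
      stop("running requires duty_factor < 50 (flight phases)",
           call. = FALSE)
  }
  structure(sc, class = "gait_scenario")
}

# per-step parameter table (mode schedule for mixed scenarios)
step_schedule <- function(sc) {
  pick <- function(mode, p) {
    v <- sc[[p]]
    if (is.null(v)) sc$defaults[[mode]][[p]] else v
  }
  mode_at <- function(tt) {
    if (sc$mode != "mixed") return(sc$mode)
    if ((floor(tt / sc$block_seconds) %% 2) == 0) "walk" else "run"
  }
  tcum <- 0; rows <- list()
  target_steps <- sc$n_steps
  repeat {
    if (!is.null(target_steps)) {
      if (length(rows) >= target_steps) break
    } else if (tcum >= sc$duration) break
    m <- mode_at(tcum)
    d0 <- 60 / pick(m, "cadence")
    d <- d0 * (1 + sc$jitter * max(-3, min(3, stats::rnorm(1))))
    rows[[length(rows) + 1]] <- data.frame(
      mode = m, duration = d, speed = pick(m, "speed"),
      vertical_amp = pick(m, "vertical_amp"),
      duty = pick(m, "duty_factor"), speed_osc = pick(m, "speed_osc"),
      lean = pick(m, "lean_deg") * pi / 180,
      lean_osc = sc$lean_osc_deg * pi / 180,
      rot = pick(m, "rotation_deg") * pi / 180,
      roll = pick(m, "roll_deg") * pi / 180,
      stringsAsFactors = FALSE)
    tcum <- tcum + d
  }
  steps <- do.call(rbind, rows)
  steps$t_start <- cumsum(c(0, steps$duration[-nrow(steps)]))
  steps$t_end <- steps$t_start + steps$duration
  steps$foot <- rep(c("left", "right"), length.out = nrow(steps))
  steps
}

#' Generate a synthetic gait trial
#'
#' Returns the emulated fused sensor stream (with sensor errors injected
#' unless `scenario$errors` is `NULL`), the insole force stream at its
#' native rate, the 400 Hz binary contact truth, and the full ground
#' truth.
#'
#' @param scenario a [gait_scenario()].
#' @return list of class `gait_trial` with elements `sensor`
#'   ([sensor_stream()]), `clean_sensor` (before error injection),
#'   `insole` ([insole_stream()]), `contact` ([contact_series()] truth on
#'   the sensor grid), `truth` (list: `steps`, `stances`, `boundaries`)
#'   and `scenario`.
#' @export
generate_gait <- function(scenario) {
  sc <- scenario
  set.seed(sc$seed)
  steps <- step_schedule(sc)
  n <- nrow(steps)
  rate <- sc$rate; dt <- 1 / rate
  t_total <- steps$t_end[n]
  t <- seq(0, t_total - dt / 2, by = dt)
  k <- findInterval(t, steps$t_start)          # step index per sample
  phi_frac <- (t - steps$t_start[k]) / steps$duration[k]
  phi <- (k - 1) + phi_frac                    # global phase, +1 per step

  # vertical velocity: -A sin(2 pi phi), A = 2 pi f * half-amplitude
  A <- 2 * pi * steps$vertical_amp[k] / steps$duration[k]
  v_up <- -A * sin(2 * pi * phi) + sc$incline_drift * t
  # speed peaks when the CoM is lowest (phi = 0.5): pendular KE/PE exchange
  speed <- steps$speed[k] - steps$speed_osc[k] * cos(2 * pi * phi)
  psi <- sc$heading + sc$heading_rate * t
  v_n <- speed * cos(psi)
  v_e <- speed * sin(psi)

  # orientation: pitch = lean, yaw = heading + stride-frequency rotation,
  # roll alternates sign with the stance foot (sin(pi*phi))
  pitch <- steps$lean[k] + steps$lean_osc[k] * sin(2 * pi * phi + pi / 3)
  yaw <- psi + steps$rot[k] * sin(pi * phi)
  roll <- steps$roll[k] * sin(pi * phi + pi / 2)
  q <- quaternion_from_euler(yaw, pitch, roll)

  # accelerations and body rates by differentiation (truth-consistent)
  a_n <- grad_series(v_n, dt)
  a_e <- grad_series(v_e, dt)
  a_up <- grad_series(v_up, dt)
  w <- body_rates_from_quat(q, dt)

  # ground truth per step
  truth_steps <- data.frame(
    step = seq_len(n), mode = steps$mode, foot = steps$foot,
    t_start = steps$t_start, t_end = steps$t_end,
    duration = steps$duration,
    t_midzero = steps$t_start + steps$duration / 2,
    speed_mean = steps$speed,
    step_length = steps$speed * steps$duration,
    speed_p2p = 2 * steps$speed_osc,
    vertical_p2p = 2 * steps$vertical_amp,
    stringsAsFactors = FALSE)

  # stances: centred at mid-step, duration = duty% of the stride
  stance_dur <- steps$duty / 100 * 2 * steps$duration
  mid <- truth_steps$t_midzero
  stances <- data.frame(
    step = seq_len(n), foot = steps$foot, mode = steps$mode,
    touchdown = mid - stance_dur / 2, toeoff = mid + stance_dur / 2,
    duration = stance_dur, stringsAsFactors = FALSE)
  # per-stance GRF amplitude: impulse = m g * step duration
  g <- 9.81
  shape_int <- ifelse(steps$mode == "walk",
                      2 / pi + sc$grf_dip * 2 / (3 * pi), 2 / pi)
  stances$amp <- sc$mass * g * steps$duration / (stance_dur * shape_int)
  stances$dip <- ifelse(steps$mode == "walk", sc$grf_dip, 0)

  grf_eval <- function(tt, foot) {
    f <- numeric(length(tt))
    sel <- which(stances$foot == foot)
    for (i in sel) {
      lo <- stances$touchdown[i]; hi <- stances$toeoff[i]
      idx <- which(tt >= lo & tt < hi)
      if (length(idx) == 0) next
      s <- (tt[idx] - lo) / (hi - lo)
      f[idx] <- f[idx] + stances$amp[i] *
        (sin(pi * s) + stances$dip[i] * sin(3 * pi * s))
    }
    f
  }
  force_l_grid <- grf_eval(t, "left")
  force_r_grid <- grf_eval(t, "right")
  contact <- contact_series(t, as.integer(force_l_grid > 0),
                            as.integer(force_r_grid > 0), rate = rate)

  t_ins <- seq(0, t_total - 1 / sc$insole_rate / 2, by = 1 / sc$insole_rate)
  fl <- grf_eval(t_ins, "left")
  fr <- grf_eval(t_ins, "right")

  if (!is.null(sc$sync_jump_at)) {
    spike <- function(tt) 50 * exp(-((tt - sc$sync_jump_at) / 0.02)^2)
    a_up <- a_up + spike(t)
    fl <- fl + 20 * sc$mass * spike(t_ins) / 50
    fr <- fr + 20 * sc$mass * spike(t_ins) / 50
  }

  clean <- sensor_stream(data.frame(
    t = t, v_north = v_n, v_east = v_e, v_down = -v_up,
    a_north = a_n, a_east = a_e, a_up = a_up,
    omega_x = w[, 1], omega_y = w[, 2], omega_z = w[, 3],
    q_w = q$q_w, q_x = q$q_x, q_y = q$q_y, q_z = q$q_z,
    pos_north = pracma::cumtrapz(t, v_n)[, 1],
    pos_east = pracma::cumtrapz(t, v_e)[, 1],
    alt = pracma::cumtrapz(t, v_up)[, 1]), rate = rate)

  sensor <- clean
  if (!is.null(sc$errors)) {
    sensor <- inject_sensor_errors(clean, sc$errors,
                                   seed = sc$seed + 7777L)
    fn <- sc$errors$force_noise_sd
    if (fn > 0) {
      fl <- pmax(fl + stats::rnorm(length(fl), sd = fn), 0)
      fr <- pmax(fr + stats::rnorm(length(fr), sd = fn), 0)
    }
  }
  insole <- insole_stream(t_ins, pmax(fl, 0), pmax(fr, 0),
                          rate = sc$insole_rate)

  structure(list(sensor = sensor, clean_sensor = clean, insole = insole,
                 contact = contact,
                 truth = list(steps = truth_steps, stances = stances,
                              boundaries = c(steps$t_start,
                                             steps$t_end[n])),
                 scenario = sc),
            class = "gait_trial")
}

# central-difference gradient (one-sided at the ends)
grad_series <- function(x, dt) {
  n <- length(x)
  g <- numeric(n)
  g[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  g[1] <- (x[2] - x[1]) / dt
  g[n] <- (x[n] - x[n - 1]) / dt
  g
}

# body angular rates from a quaternion series: omega = 2 * vec(q^-1 * dq/dt)
body_rates_from_quat <- function(q, dt) {
  n <- nrow(q)
  dq <- sapply(q, function(col) grad_series(col, dt))
  qw <- q$q_w; qx <- q$q_x; qy <- q$q_y; qz <- q$q_z
  dw <- dq[, "q_w"]; dx <- dq[, "q_x"]; dy <- dq[, "q_y"]; dz <- dq[, "q_z"]
  # quaternion product conj(q) * dq, vector part
  wx <- 2 * (qw * dx - qx * dw - qy * dz + qz * dy)
  wy <- 2 * (qw * dy + qx * dz - qy * dw - qz * dx)
  wz <- 2 * (qw * dz - qx * dy + qy * dx - qz * dw)
  cbind(wx, wy, wz)
}

#' Inject sensor errors into a clean stream
#'
#' Applies the [error_model()]: accelerometer bias + white noise at the
#' stated density + quadratic nonlinearity `a * (1 + alpha * a / FS)`;
#' bounded, zero-mean velocity error (slow wander plus white noise,
#' clipped at the bound) on each velocity axis; small orientation noise
#' re-composed into the quaternion; gyro white noise.
#'
#' @param stream a clean [sensor_stream()].
#' @param model an [error_model()].
#' @param seed RNG seed.
#' @return a corrupted [sensor_stream()].
#' @export
inject_sensor_errors <- function(stream, model, seed = 1) {
  set.seed(seed)
  n <- nrow(stream)
  rate <- attr(stream, "rate")
  dt <- 1 / rate
  out <- as.data.frame(stream)

  sigma_a <- model$accel_noise_density * sqrt(rate / 2)
  nl <- function(a) a * (1 + model$accel_nonlinearity *
                           a / model$accel_full_scale)
  bias <- model$accel_bias * sample(c(-1, 1), 3, replace = TRUE)
  out$a_north <- nl(out$a_north) + bias[1] + stats::rnorm(n, sd = sigma_a)
  out$a_east <- nl(out$a_east) + bias[2] + stats::rnorm(n, sd = sigma_a)
  out$a_up <- nl(out$a_up) + bias[3] + stats::rnorm(n, sd = sigma_a)

  vel_err <- function() {
    phi <- exp(-dt / model$vel_wander_tau)
    innov_sd <- model$vel_wander_sd * sqrt(1 - phi^2)
    wander <- as.numeric(stats::filter(stats::rnorm(n, sd = innov_sd),
                                       phi, method = "recursive"))
    e <- wander + stats::rnorm(n, sd = model$vel_white_sd)
    pmin(pmax(e, -model$vel_bound), model$vel_bound)
  }
  out$v_north <- out$v_north + vel_err()
  out$v_east <- out$v_east + vel_err()
  out$v_down <- out$v_down + vel_err()

  att_err <- function(sd_deg, tau = 5) {
    phi <- exp(-dt / tau)
    innov <- sd_deg * pi / 180 * sqrt(1 - phi^2)
    as.numeric(stats::filter(stats::rnorm(n, sd = innov), phi,
                             method = "recursive"))
  }
  eul <- euler_from_quaternion(out$q_w, out$q_x, out$q_y, out$q_z)
  q2 <- quaternion_from_euler(eul$yaw + att_err(model$heading_noise_deg),
                              eul$pitch + att_err(model$att_noise_deg),
                              eul$roll + att_err(model$att_noise_deg))
  nq <- sqrt(q2$q_w^2 + q2$q_x^2 + q2$q_y^2 + q2$q_z^2)
  out$q_w <- q2$q_w / nq; out$q_x <- q2$q_x / nq
  out$q_y <- q2$q_y / nq; out$q_z <- q2$q_z / nq

  for (col in c("omega_x", "omega_y", "omega_z"))
    out[[col]] <- out[[col]] + stats::rnorm(n, sd = model$gyro_noise_sd)

  sensor_stream(out, rate = rate)
}

#' Compare detected step segments against generator ground truth
#'
#' Matches each regular detected step to the nearest ground-truth step
#' start and reports timing errors; the validation counterpart of
#' [generate_gait()].
#'
#' @param segments a [segment_steps()] table (only `"regular"` rows are
#'   compared).
#' @param truth_steps the `truth$steps` table of a generated trial.
#' @return data.frame `step`, `truth_step`, `start_error` and
#'   `duration_error` (seconds, detected minus truth).
#' @export
segmentation_errors <- function(segments, truth_steps) {
  reg <- segments[segments$quality_flag == "regular", , drop = FALSE]
  idx <- vapply(reg$t_start,
                function(x) which.min(abs(x - truth_steps$t_start)),
                integer(1))
  data.frame(step = reg$step, truth_step = idx,
             start_error = reg$t_start - truth_steps$t_start[idx],
             duration_error = reg$duration - truth_steps$duration[idx])
}
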