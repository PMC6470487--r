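# Per-step gait metrics.
#
# Every metric is computed over one step segment [t_start, t_end).
# Integrals are trapezoidal on the sample grid with linearly interpolated
# fractional end intervals, so that per-step distances telescope exactly
# into the whole-trial integral.

# linear interpolation at arbitrary times (vectorized, O(1) per point)
interp_at <- function(t, y, x) {
  i <- pmin(pmax(findInterval(x, t), 1L), length(t) - 1L)
  y[i] + (y[i + 1] - y[i]) * (x - t[i]) / (t[i + 1] - t[i])
}

# exact integral of the linear interpolant of (t, y) from t[1] to x,
# given the cumulative trapezoidal integral at the samples
cum_integral_at <- function(t, y, cumint, x) {
  i <- pmin(pmax(findInterval(x, t), 1L), length(t) - 1L)
  yx <- y[i] + (y[i + 1] - y[i]) * (x - t[i]) / (t[i + 1] - t[i])
  cumint[i] + (x - t[i]) * (y[i] + yx) / 2
}

# integral of the linear interpolant of (t, y) over [t0, t1]
trapz_between <- function(t, y, t0, t1, cumint = NULL) {
  if (any(t0 < t[1] - 1e-9) || any(t1 > t[length(t)] + 1e-9))
    stop("integration interval outside the stream span", call. = FALSE)
  if (is.null(cumint)) cumint <- pracma::cumtrapz(t, y)[, 1]
  cum_integral_at(t, y, cumint, t1) - cum_integral_at(t, y, cumint, t0)
}

#' Step length: distance travelled during one step
#'
#' Trapezoidal integral of horizontal speed over the step interval.
#'
#' @param speed horizontal speed series, m/s.
#' @param t time, seconds.
#' @param seg one row of a [segment_steps()] table (or a list with
#'   `t_start`, `t_end`).
#' @param cumint optional precomputed `pracma::cumtrapz(t, speed)` column
#'   (avoids recomputation across many steps).
#' @return metres.
#' @export
step_length <- function(speed, t, seg, cumint = NULL) {
  trapz_between(t, speed, seg$t_start, seg$t_end, cumint)
}

#' Vertical displacement by integrating vertical velocity
#'
#' Cumulative trapezoidal integration of the (drift-filtered) vertical
#' velocity over a window covering an integer number of steps. The
#' oscillation is referenced to the nominal height, taken as the window
#' mean of the integrated displacement. Per step, the peak-to-peak
#' displacement (vertical oscillation) and the closure residual (the
#' displacement change from step start to step end, zero for ideal
#' periodic gait on level ground, hence an error estimate) are reported.
#'
#' @param v_filtered filtered vertical velocity, m/s.
#' @param t time, seconds.
#' @param segments a [segment_steps()] table; the window is taken from the
#'   start of the first to the end of the last listed segment.
#' @return list with `series` (data.frame `t`, `h`: displacement about the
#'   window mean, metres) and `per_step` (data.frame `step`, `p2p`,
#'   `closure`).
#' @export
vertical_displacement <- function(v_filtered, t, segments) {
  h <- pracma::cumtrapz(t, as.numeric(v_filtered))[, 1]
  if (nrow(segments) > 0) {
    lo <- min(segments$t_start); hi <- max(segments$t_end)
    win <- t >= lo & t < hi
    h <- h - mean(h[win])
  } else {
    h <- h - mean(h)
  }
  per <- data.frame(step = segments$step,
                    p2p = NA_real_, closure = NA_real_)
  for (k in seq_len(nrow(segments))) {
    i0 <- segments$i_start[k]; i1 <- segments$i_end[k]
    hs <- interp_at(t, h, segments$t_start[k])
    he <- interp_at(t, h, segments$t_end[k])
    vals <- c(hs, h[i0:i1], he)
    per$p2p[k] <- max(vals) - min(vals)
    per$closure[k] <- he - hs
  }
  list(series = data.frame(t = t, h = h), per_step = per)
}

#' Peak-to-peak speed difference within one step
#'
#' @param speed horizontal speed series, m/s.
#' @param t time, seconds.
#' @param seg one segment row.
#' @return max minus min of speed inside the step, m/s.
#' @export
speed_p2p <- function(speed, t, seg) {
  vals <- c(interp_at(t, speed, seg$t_start),
            speed[seg$i_start:seg$i_end],
            interp_at(t, speed, seg$t_end))
  max(vals) - min(vals)
}

#' Forward lean over one step
#'
#' Mean sagittal-plane angle between the body axis and the vertical,
#' forward-positive, in degrees. The within-step statistic is the mean.
#'
#' @param pitch pitch series, radians (forward lean positive).
#' @param t time, seconds.
#' @param seg one segment row.
#' @return degrees.
#' @export
forward_lean <- function(pitch, t, seg) {
  mean(pitch[seg$i_start:seg$i_end]) * 180 / pi
}

#' Body rotation amplitude over one step
#'
#' Peak-to-peak amplitude of rotation about the vertical axis, measured as
#' yaw relative to the ground track (so a curved path does not register as
#' trunk rotation). Both angles are unwrapped before differencing; the
#' result is invariant to any constant heading offset.
#'
#' @param yaw yaw series, radians.
#' @param track ground-track series, radians.
#' @param t time, seconds.
#' @param seg one segment row.
#' @return degrees.
#' @export
body_rotation <- function(yaw, track, t, seg) {
  idx <- seg$i_start:seg$i_end
  rel <- unwrap_angle(yaw[idx]) - unwrap_angle(track[idx])
  (max(rel) - min(rel)) * 180 / pi
}

unwrap_angle <- function(x) {
  if (length(x) < 2) return(x)
  d <- diff(x)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(x[1], x[1] + cumsum(d))
}

#' Contact time, duty factor, flight time and flight distance
#'
#' The stance assigned to a step is the one whose midpoint falls inside
#' the step. Contact time is that stance's full duration; the duty factor
#' expresses it as a percentage of step duration (in walking, where the
#' stance spans more than one step, this exceeds 100%). Flight is the part
#' of the step where neither foot is on the ground (running only).
#'
#' @param contact a [contact_series()] aligned to the stream grid.
#' @param speed horizontal speed series, m/s (same grid).
#' @param t time, seconds.
#' @param seg one segment row.
#' @param min_stance stances shorter than this are ignored, seconds.
#' @return list with `contact_time` (s), `duty_factor` (%),
#'   `flight_time` (s), `flight_distance` (m), `foot` (`"left"`/`"right"`),
#'   all `NA` when no stance midpoint falls in the step.
#' @export
duty_and_flight <- function(contact, speed, t, seg, min_stance = 0.04) {
  rate <- attr(contact, "rate") %||% (1 / stats::median(diff(contact$t)))
  runs_for <- function(x, foot) {
    df <- contact_runs(x, contact$t, rate, min_stance)
    df$foot <- rep(foot, nrow(df))
    df
  }
  stances <- rbind(runs_for(contact$contact_left, "left"),
                   runs_for(contact$contact_right, "right"))
  out <- list(contact_time = NA_real_, duty_factor = NA_real_,
              flight_time = NA_real_, flight_distance = NA_real_,
              foot = NA_character_)
  if (nrow(stances) > 0) {
    mid <- (stances$touchdown + stances$toeoff) / 2
    inside <- which(mid >= seg$t_start & mid < seg$t_end)
    if (length(inside) > 0) {
      if (length(inside) > 1) {   # keep the stance overlapping the step most
        ov <- pmin(stances$toeoff[inside], seg$t_end) -
          pmax(stances$touchdown[inside], seg$t_start)
        inside <- inside[which.max(ov)]
      }
      out$contact_time <- stances$duration[inside]
      out$duty_factor <- 100 * out$contact_time / seg$duration
      out$foot <- stances$foot[inside]
    }
  }
  # flight: both feet off the ground
  idx <- seg$i_start:seg$i_end
  airborne <- contact$contact_left[idx] == 0 & contact$contact_right[idx] == 0
  dt <- 1 / rate
  out$flight_time <- sum(airborne) * dt
  out$flight_distance <- sum(speed[idx] * airborne) * dt
  out
}

# run-length encode 1-runs of a binary series into stance intervals
contact_runs <- function(x, t, rate, min_duration = 0.04) {
  r <- rle(as.integer(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  on <- which(r$values == 1L & r$lengths / rate >= min_duration)
  data.frame(touchdown = t[starts[on]],
             toeoff = t[starts[on]] + r$lengths[on] / rate,
             duration = r$lengths[on] / rate)
}

#' Total mechanical energy over one step
#'
#' Mean over the step of kinetic plus potential energy,
#' `0.5*m*(V^2 + v_z^2) + m*g*h`, with `h` the vertical displacement about
#' the window mean.
#'
#' @param speed horizontal speed, m/s.
#' @param v_vertical vertical velocity, m/s.
#' @param h vertical displacement about the window mean, m (from
#'   [vertical_displacement()]).
#' @param t time, seconds.
#' @param seg one segment row.
#' @param mass subject mass, kg.
#' @param g gravitational acceleration, m/s^2.
#' @return joules, or `NA` if `mass` is `NULL`/`NA`.
#' @export
mech_energy <- function(speed, v_vertical, h, t, seg, mass, g = 9.81) {
  if (is.null(mass) || is.na(mass)) return(NA_real_)
  if (mass <= 0) stop("mass must be positive", call. = FALSE)
  idx <- seg$i_start:seg$i_end
  mean(0.5 * mass * (speed[idx]^2 + v_vertical[idx]^2) + mass * g * h[idx])
}

#' Speed averaged over rolling distance windows
#'
#' For each requested distance `D`, the mean speed `D / (time to traverse
#' D)` starting at each step boundary. Boundaries from which the remaining
#' trial is shorter than `D` get `NA`.
#'
#' @param speed horizontal speed, m/s (must be positive for the distance
#'   axis to be invertible).
#' @param t time, seconds.
#' @param at_times times at which windows start (typically step starts).
#' @param distances target distances, metres.
#' @return data.frame `t_start`, `distance`, `speed`.
#' @export
windowed_speed <- function(speed, t, at_times, distances = c(10, 20, 50)) {
  cd <- pracma::cumtrapz(t, speed)[, 1]
  out <- expand.grid(t_start = at_times, distance = distances,
                     KEEP.OUT.ATTRS = FALSE)
  s0 <- stats::approx(t, cd, xout = out$t_start)$y
  target <- s0 + out$distance
  t1 <- stats::approx(cd, t, xout = target, ties = "ordered")$y
  out$speed <- out$distance / (t1 - out$t_start)
  out
}

#' Per-step metrics table
#'
#' Computes the full metric set for every regular step: cadence, duration,
#' step length, mean speed (= length/duration), peak-to-peak speed,
#' vertical oscillation and closure residual, forward lean, body rotation,
#' and (when inputs are available) contact time, duty factor, flight time,
#' flight distance, and total mechanical energy.
#'
#' @param anatomical an [anatomical_series()].
#' @param v_filtered filtered vertical velocity (same grid).
#' @param segments a [segment_steps()] table; only rows flagged
#'   `"regular"` are evaluated.
#' @param contact optional [contact_series()] on the same grid.
#' @param mass optional subject mass, kg.
#' @param g gravitational acceleration, m/s^2.
#' @return data.frame with one row per regular step.
#' @export
step_metrics_table <- function(anatomical, v_filtered, segments,
                               contact = NULL, mass = NULL, g = 9.81) {
  segs <- segments[segments$quality_flag == "regular", , drop = FALSE]
  t <- anatomical$t
  vd <- vertical_displacement(v_filtered, t, segs)
  n <- nrow(segs)
  out <- data.frame(step = segs$step, t_start = segs$t_start,
                    t_end = segs$t_end, duration = segs$duration,
                    cadence = 60 / segs$duration,
                    step_length = NA_real_, speed_mean = NA_real_,
                    speed_p2p = NA_real_, vertical_p2p = vd$per_step$p2p,
                    vertical_closure = vd$per_step$closure,
                    forward_lean = NA_real_, body_rotation = NA_real_)
  if (!is.null(contact)) {
    out$contact_time <- out$duty_factor <- out$flight_time <-
      out$flight_distance <- NA_real_
    out$foot <- NA_character_
  }
  if (!is.null(mass)) out$mech_energy <- NA_real_
  speed_cum <- pracma::cumtrapz(t, anatomical$speed)[, 1]
  for (k in seq_len(n)) {
    seg <- segs[k, ]
    out$step_length[k] <- step_length(anatomical$speed, t, seg, speed_cum)
    out$speed_mean[k] <- out$step_length[k] / seg$duration
    out$speed_p2p[k] <- speed_p2p(anatomical$speed, t, seg)
    out$forward_lean[k] <- forward_lean(anatomical$pitch, t, seg)
    out$body_rotation[k] <- body_rotation(anatomical$yaw, anatomical$track,
                                          t, seg)
    if (!is.null(contact)) {
      df <- duty_and_flight(contact, anatomical$speed, t, seg)
      out$contact_time[k] <- df$contact_time
      out$duty_factor[k] <- df$duty_factor
      out$flight_time[k] <- df$flight_time
      out$flight_distance[k] <- df$flight_distance
      out$foot[k] <- df$foot
    }
    if (!is.null(mass))
      out$mech_energy[k] <- mech_energy(anatomical$speed,
                                        anatomical$v_vertical,
                                        vd$series$h, t, seg, mass, g)
  }
  out
}
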