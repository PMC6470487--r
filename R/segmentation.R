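# Step segmentation from filtered vertical velocity.
#
# A step starts when the vertical velocity crosses zero going negative
# (the centre of mass at its apex); the downward-to-upward crossing inside
# the step marks the lowest CoM point. Crossing times are estimated to
# sub-sample precision because the timing budget (5 ms) is finer than the
# 2.5 ms sample interval.

#' Locate zero crossings of a filtered vertical-velocity series
#'
#' Sign changes are refined to sub-sample times by a local least-squares
#' line fit (falling back to two-point interpolation when the fit root
#' leaves the bracketing interval). Crossings are gated on amplitude: the
#' signal must exceed `+threshold` before and fall below `-threshold`
#' after a negative-going crossing (mirrored for positive-going), which
#' suppresses micro-oscillations around zero. Crossings of the same
#' direction closer than the refractory interval are merged, keeping the
#' steepest.
#'
#' @param v filtered vertical velocity, m/s.
#' @param t time, seconds.
#' @param threshold near-zero amplitude gate, m/s.
#' @param refractory minimum spacing between same-direction crossings,
#'   seconds (shorter than any plausible half step).
#' @param fit_halfwidth samples on each side of the crossing used in the
#'   line fit.
#' @return data.frame with columns `time`, `direction` (-1 negative-going,
#'   +1 positive-going) and `slope` (m/s^2), sorted by time. May be empty.
#' @export
find_zero_crossings <- function(v, t, threshold = 0.02, refractory = 0.15,
                                fit_halfwidth = 3) {
  n <- length(v)
  if (n < 2) return(empty_crossings())
  neg <- which(v[-n] > 0 & v[-1] <= 0)
  pos <- which(v[-n] < 0 & v[-1] >= 0)
  res <- rbind(refine_crossings(v, t, neg, -1, threshold, refractory,
                                fit_halfwidth),
               refine_crossings(v, t, pos, +1, threshold, refractory,
                                fit_halfwidth))
  res <- res[order(res$time), , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_crossings <- function() {
  data.frame(time = numeric(0), direction = numeric(0), slope = numeric(0))
}

refine_crossings <- function(v, t, idx, direction, threshold, refractory,
                             hw) {
  if (length(idx) == 0) return(empty_crossings())
  n <- length(v)
  dt <- stats::median(diff(t))
  ref_n <- max(1L, round(refractory / dt))
  times <- numeric(length(idx)); slopes <- numeric(length(idx))
  keep <- logical(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    # amplitude gate over the surrounding refractory spans
    before <- v[max(1, i - ref_n):i]
    after <- v[(i + 1):min(n, i + 1 + ref_n)]
    if (direction < 0) {
      if (max(before) < threshold || min(after) > -threshold) next
    } else {
      if (min(before) > -threshold || max(after) < threshold) next
    }
    lo <- max(1, i - hw + 1); hi <- min(n, i + hw)
    tt <- t[lo:hi] - t[i]; vv <- v[lo:hi]
    sxx <- sum((tt - mean(tt))^2)
    slope <- sum((tt - mean(tt)) * (vv - mean(vv))) / sxx
    root <- t[i] + (mean(tt) - mean(vv) / slope)
    # two-point fallback when the fit root leaves the bracket
    if (!is.finite(root) || root < t[i] || root > t[i + 1]) {
      root <- t[i] + v[i] / (v[i] - v[i + 1]) * (t[i + 1] - t[i])
      slope <- (v[i + 1] - v[i]) / (t[i + 1] - t[i])
    }
    times[k] <- root; slopes[k] <- slope; keep[k] <- TRUE
  }
  times <- times[keep]; slopes <- slopes[keep]
  if (length(times) == 0) return(empty_crossings())
  # merge clusters closer than the refractory interval, keep steepest
  cl <- cumsum(c(1, diff(times) >= refractory))
  sel <- vapply(split(seq_along(times), cl), function(ii) {
    ii[which.max(abs(slopes[ii]))]
  }, integer(1))
  data.frame(time = times[sel], direction = direction, slope = slopes[sel])
}

#' Segment a gait trial into steps
#'
#' One step per pair of consecutive negative-going zero crossings of the
#' filtered vertical velocity; the positive-going crossing between them is
#' the mid-step (CoM lowest) instant. Partial steps at the window edges
#' are dropped by construction. Steps that start or end inside the filter
#' warm-up region (`edge_guard` seconds from either end) are flagged
#' irregular rather than trusted.
#'
#' @param v filtered vertical velocity (see
#'   [highpass_vertical_velocity()]); if it carries an `edge_guard_s`
#'   attribute that is used as the default `edge_guard`.
#' @param t time, seconds.
#' @param threshold,refractory,fit_halfwidth passed to
#'   [find_zero_crossings()].
#' @param edge_guard seconds near the stream edges within which steps are
#'   flagged `"irregular"`.
#' @return data.frame of class `step_segments`: `step`, `t_start`,
#'   `t_end`, `i_start`, `i_end` (sample index range), `t_midzero`,
#'   `duration`, `quality_flag` (`"regular"`/`"irregular"`). Empty (with a
#'   warning) when fewer than two negative-going crossings exist.
#' @export
segment_steps <- function(v, t, threshold = 0.02, refractory = 0.15,
                          fit_halfwidth = 3,
                          edge_guard = attr(v, "edge_guard_s") %||% 0) {
  cr <- find_zero_crossings(v, t, threshold, refractory, fit_halfwidth)
  neg <- cr$time[cr$direction < 0]
  posc <- cr[cr$direction > 0, , drop = FALSE]
  if (length(neg) < 2) {
    warning("fewer than two negative-going crossings; no complete steps")
    return(empty_segments())
  }
  ns <- length(neg) - 1
  t_start <- neg[-length(neg)]
  t_end <- neg[-1]
  t_mid <- rep(NA_real_, ns)
  for (k in seq_len(ns)) {
    inside <- which(posc$time > t_start[k] & posc$time < t_end[k])
    if (length(inside) == 1) {
      t_mid[k] <- posc$time[inside]
    } else if (length(inside) > 1) {
      t_mid[k] <- posc$time[inside[which.max(abs(posc$slope[inside]))]]
    }
  }
  i_start <- findInterval(t_start, t) + 1L
  i_end <- findInterval(t_end, t)
  i_end[t[pmax(i_end, 1L)] == t_end] <- i_end[t[pmax(i_end, 1L)] == t_end] - 1L
  flag <- rep("regular", ns)
  flag[is.na(t_mid)] <- "irregular"
  if (edge_guard > 0) {
    lo <- t[1] + edge_guard
    hi <- t[length(t)] - edge_guard
    flag[t_start < lo | t_end > hi] <- "irregular"
  }
  structure(data.frame(step = seq_len(ns), t_start = t_start, t_end = t_end,
                       i_start = i_start, i_end = i_end, t_midzero = t_mid,
                       duration = t_end - t_start, quality_flag = flag,
                       stringsAsFactors = FALSE),
            class = c("step_segments", "data.frame"))
}

empty_segments <- function() {
  structure(data.frame(step = integer(0), t_start = numeric(0),
                       t_end = numeric(0), i_start = integer(0),
                       i_end = integer(0), t_midzero = numeric(0),
                       duration = numeric(0),
                       quality_flag = character(0),
                       stringsAsFactors = FALSE),
            class = c("step_segments", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flag steps recorded during irregular motion
#'
#' Segments recorded during motion that is neither walking nor running are
#' excluded from metrics. A segment is flagged irregular when any of:
#' its duration leaves `duration_range`; the vertical-velocity peak-to-peak
#' amplitude inside it falls below `min_amplitude`; or its duration
#' deviates from the median of the trailing `median_window` step durations
#' by more than `max_rel_dev` (applied once at least 3 previous steps
#' exist).
#'
#' @param segments a [segment_steps()] table.
#' @param v filtered vertical velocity used for segmentation.
#' @param t time, seconds.
#' @param duration_range admissible step duration, seconds.
#' @param min_amplitude minimum vertical-velocity peak-to-peak, m/s.
#' @param median_window trailing window length, steps.
#' @param max_rel_dev maximum relative deviation from the trailing median.
#' @return the segments table with `quality_flag` updated.
#' @export
reject_irregular <- function(segments, v, t,
                             duration_range = c(0.2, 1.5),
                             min_amplitude = 0.1,
                             median_window = 5, max_rel_dev = 0.4) {
  if (nrow(segments) == 0) return(segments)
  dur <- segments$duration
  flag <- segments$quality_flag
  flag[dur < duration_range[1] | dur > duration_range[2]] <- "irregular"
  for (k in seq_len(nrow(segments))) {
    vv <- v[segments$i_start[k]:segments$i_end[k]]
    if (length(vv) == 0 || diff(range(vv)) < min_amplitude)
      flag[k] <- "irregular"
    if (k > 3) {
      prev <- dur[max(1, k - median_window):(k - 1)]
      med <- stats::median(prev)
      if (abs(dur[k] - med) > max_rel_dev * med) flag[k] <- "irregular"
    }
  }
  segments$quality_flag <- flag
  segments
}

#' Run the full segmentation pipeline on a sensor stream
#'
#' Convenience wrapper: anatomical kinematics, vertical-velocity high-pass
#' filtering, zero-crossing segmentation and irregular-motion rejection.
#'
#' @param stream a [sensor_stream()].
#' @param filter a [filter_spec()].
#' @param stall_threshold see [compute_ground_track()].
#' @param threshold,refractory see [find_zero_crossings()].
#' @param ... passed on to [reject_irregular()].
#' @return list with `anatomical` (the [anatomical_series()]),
#'   `v_filtered` (filtered vertical velocity) and `segments`.
#' @export
segment_gait <- function(stream, filter = filter_spec(),
                         stall_threshold = 0.3, threshold = 0.02,
                         refractory = 0.15, ...) {
  anat <- anatomical_series(stream, stall_threshold)
  rate <- attr(stream, "rate")
  vf <- highpass_vertical_velocity(anat$v_vertical, rate, filter)
  seg <- segment_steps(vf, anat$t, threshold, refractory)
  seg <- reject_irregular(seg, vf, anat$t, ...)
  list(anatomical = anat, v_filtered = vf, segments = seg)
}
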