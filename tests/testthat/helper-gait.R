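# Shared fixtures, built in code.

# quiet wrapper: segment_gait logs nothing, but the shift experiment
# messages about dropped edge steps
quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# a clean (error-free, jitter-free) walking trial for exact oracles
clean_walk <- function(n_steps = 40, seed = 101, ...) {
  generate_gait(gait_scenario("walk", n_steps = n_steps, jitter = 0,
                              errors = NULL, seed = seed, ...))
}

# a short synthetic anatomical series built directly (no generator),
# for metric unit tests with closed-form answers
flat_anatomical <- function(t, speed, v_vertical = 0 * t, pitch = 0 * t,
                            yaw = 0 * t, track = 0 * t, rate = 400) {
  structure(data.frame(t = t, speed = speed, track = track,
                       a_forward = 0 * t, v_vertical = v_vertical,
                       a_vertical = 0 * t, pitch = pitch, yaw = yaw,
                       roll = 0 * t),
            class = c("anatomical_series", "data.frame"), rate = rate)
}

# independent brute-force trapezoid on a dense sub-grid
trapz_between_oracle <- function(t, y, t0, t1) {
  g <- seq(t0, t1, length.out = 200001)
  yy <- approx(t, y, xout = g)$y
  sum(diff(g) * (yy[-1] + yy[-length(yy)]) / 2)
}

# one manually specified step segment
manual_segment <- function(t, t_start, t_end, t_mid = (t_start + t_end) / 2) {
  i_start <- findInterval(t_start, t) + 1L
  i_end <- findInterval(t_end, t)
  if (t[max(i_end, 1L)] == t_end) i_end <- i_end - 1L
  data.frame(step = 1L, t_start = t_start, t_end = t_end,
             i_start = i_start, i_end = i_end, t_midzero = t_mid,
             duration = t_end - t_start, quality_flag = "regular",
             stringsAsFactors = FALSE)
}
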