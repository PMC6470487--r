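# Drift removal from vertical velocity.
#
# Vertical velocity from a fused INS/GPS carries low-frequency drift
# (residual accelerometer bias, inclined terrain). Step segmentation keys
# on zero crossings, so the drift is removed with a zero-phase FIR
# high-pass designed to a (passband edge, stopband attenuation, steepness)
# triple; phase fidelity is what matters, since any group delay would move
# every crossing.

#' High-pass filter specification
#'
#' The passband edge is expressed as a fraction of Nyquist (a normalized
#' frequency of `0.005` at 400 Hz puts the edge at 1 Hz, below the slowest
#' plausible step frequency). `steepness` sets the transition width as
#' `(1 - steepness) * passband_edge_hz`: the transition band occupies the
#' remaining fraction of the interval between DC and the passband edge.
#'
#' @param passband_edge passband edge as a fraction of Nyquist, in (0, 1).
#' @param stopband_atten minimum stopband attenuation, dB.
#' @param steepness transition steepness in [0.5, 1).
#' @param zero_phase apply the filter forward-backward (exactly zero
#'   phase). `FALSE` applies a single delay-compensated pass, which is
#'   also zero-phase for this symmetric FIR but with half the stopband
#'   attenuation.
#' @return list of class `filter_spec`.
#' @export
filter_spec <- function(passband_edge = 0.005, stopband_atten = 30,
                        steepness = 0.7, zero_phase = TRUE) {
  stopifnot(passband_edge > 0, passband_edge < 1, stopband_atten > 0,
            steepness >= 0.5, steepness < 1)
  structure(list(passband_edge = passband_edge,
                 stopband_atten = stopband_atten,
                 steepness = steepness, zero_phase = zero_phase),
            class = "filter_spec")
}

#' Design the minimum-order high-pass FIR for a filter spec
#'
#' Kaiser-window design: the window beta and the filter order follow the
#' standard Kaiser formulas for the requested attenuation and the
#' transition width implied by `steepness`, giving the shortest linear-
#' phase FIR meeting the spec.
#'
#' @param spec a [filter_spec()].
#' @param rate sample rate, Hz.
#' @return list with `b` (coefficients, odd length), `n_taps`,
#'   `edge_guard_s` (warm-up span at each end, seconds), `f_pass`,
#'   `f_stop` (Hz).
#' @export
design_highpass <- function(spec, rate = 400) {
  nyq <- rate / 2
  f_pass <- spec$passband_edge * nyq
  tw <- (1 - spec$steepness) * f_pass
  f_stop <- f_pass - tw
  a <- spec$stopband_atten
  beta <- if (a > 50) {
    0.1102 * (a - 8.7)
  } else if (a >= 21) {
    0.5842 * (a - 21)^0.4 + 0.07886 * (a - 21)
  } else 0
  dw <- 2 * pi * tw / rate
  n <- ceiling((a - 7.95) / (2.285 * dw))
  if (n %% 2 == 1) n <- n + 1            # even order -> odd length (type I)
  wc <- (f_pass + f_stop) / 2 / nyq
  b <- signal::fir1(n, wc, type = "high", window = signal::kaiser(n + 1, beta))
  list(b = as.numeric(b), n_taps = n + 1,
       edge_guard_s = (n + 1) / rate, f_pass = f_pass, f_stop = f_stop)
}

# One delay-compensated pass of a linear-phase FIR (odd length).
# Edges are padded by odd reflection to suppress the startup transient.
fir_zero_phase_pass <- function(b, x) {
  n <- length(b)
  pad <- n
  nx <- length(x)
  if (nx <= pad + 1)
    stop("series too short for edge padding", call. = FALSE)
  pre <- 2 * x[1] - x[(pad + 1):2]
  post <- 2 * x[nx] - x[(nx - 1):(nx - pad)]
  xp <- c(pre, x, post, numeric(n))
  y <- signal::fftfilt(b, xp)
  delay <- (n - 1) / 2
  y[(pad + delay + 1):(pad + delay + nx)]
}

#' High-pass filter a vertical-velocity series
#'
#' Removes DC and sub-passband drift while preserving the timing of
#' in-band zero crossings: the symmetric FIR is applied with its group
#' delay compensated (twice, i.e. forward-backward, when
#' `spec$zero_phase`), so a pure in-band sinusoid's crossings move by less
#' than one sample.
#'
#' @param v vertical velocity, m/s, up-positive.
#' @param rate sample rate, Hz.
#' @param spec a [filter_spec()].
#' @return the filtered series, with attributes `edge_guard_s` (seconds of
#'   warm-up at each end that downstream steps should treat as unreliable)
#'   and `rate`.
#' @export
highpass_vertical_velocity <- function(v, rate = 400, spec = filter_spec()) {
  des <- design_highpass(spec, rate)
  if (length(v) <= 3 * des$n_taps)
    stop(sprintf("series of length %d is too short to filter; need more than %d samples (3 filter lengths)",
                 length(v), 3 * des$n_taps), call. = FALSE)
  y <- fir_zero_phase_pass(des$b, v)
  if (isTRUE(spec$zero_phase)) y <- fir_zero_phase_pass(des$b, y)
  attr(y, "edge_guard_s") <- des$edge_guard_s
  attr(y, "rate") <- rate
  y
}
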