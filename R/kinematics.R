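# NED-to-anatomical-frame kinematics.
#
# For walking/running on level terrain the anatomical transformation is
# well approximated by the horizontal speed V = sqrt(vN^2 + vE^2), the
# ground track (heading of travel), the magnitude of horizontal
# acceleration, and the up-positive vertical components.

#' Horizontal speed from NED velocity components
#'
#' @param v_north,v_east velocity components, m/s, equal length.
#' @return elementwise `sqrt(v_north^2 + v_east^2)`, m/s.
#' @export
compute_speed <- function(v_north, v_east) {
  if (length(v_north) != length(v_east))
    stop("v_north and v_east must have equal length", call. = FALSE)
  sqrt(v_north^2 + v_east^2)
}

#' Ground track (direction of travel) from NED velocity
#'
#' Four-quadrant angle of the horizontal velocity, radians in (-pi, pi],
#' measured from north, positive towards east. Heading from velocity is
#' meaningless near standstill, so samples with speed below
#' `stall_threshold` hold the last valid track (leading stalled samples
#' take the first valid value; an all-stalled series returns zeros).
#'
#' @param v_north,v_east velocity components, m/s.
#' @param stall_threshold speed below which the track is held, m/s.
#' @return track angle series, radians.
#' @export
compute_ground_track <- function(v_north, v_east, stall_threshold = 0.3) {
  if (length(v_north) != length(v_east))
    stop("v_north and v_east must have equal length", call. = FALSE)
  psi <- atan2(v_east, v_north)
  v <- sqrt(v_north^2 + v_east^2)
  ok <- v >= stall_threshold
  if (!any(ok)) return(rep(0, length(psi)))
  psi[!ok] <- NA_real_
  locf_fill(psi)
}

locf_fill <- function(x) {
  ok <- !is.na(x)
  first <- which(ok)[1]
  if (first > 1) x[seq_len(first - 1)] <- x[first]
  idx <- cummax(ifelse(is.na(x), 0L, seq_along(x)))
  idx[idx == 0L] <- first
  x[idx]
}

#' Forward acceleration magnitude
#'
#' Magnitude of the horizontal acceleration components; the anatomical
#' forward-axis acceleration for motion along the direction of progression.
#'
#' @param a_north,a_east horizontal acceleration components, m/s^2.
#' @return non-negative series, m/s^2.
#' @export
compute_forward_acceleration <- function(a_north, a_east) {
  if (length(a_north) != length(a_east))
    stop("a_north and a_east must have equal length", call. = FALSE)
  sqrt(a_north^2 + a_east^2)
}

#' Up-positive vertical component from a NED down component
#'
#' @param v_down the down-positive NED component.
#' @return the sign-flipped (up-positive) series.
#' @export
vertical_from_ned <- function(v_down) -v_down

#' Euler angles from orientation quaternions
#'
#' Aerospace Z-Y-X (yaw-pitch-roll) extraction from unit quaternions in
#' w,x,y,z order. Yaw in (-pi, pi], pitch in [-pi/2, pi/2], roll in
#' (-pi, pi].
#'
#' @param q_w,q_x,q_y,q_z quaternion components, unit norm.
#' @param tol largest tolerated deviation of |q| from 1.
#' @return data.frame with columns `yaw`, `pitch`, `roll` (radians).
#' @export
euler_from_quaternion <- function(q_w, q_x, q_y, q_z, tol = 1e-6) {
  n <- sqrt(q_w^2 + q_x^2 + q_y^2 + q_z^2)
  bad <- which(abs(n - 1) > tol)
  if (length(bad) > 0)
    stop(sprintf("non-unit quaternion at sample %d (|q| = %.9f)",
                 bad[1], n[bad[1]]), call. = FALSE)
  yaw <- atan2(2 * (q_w * q_z + q_x * q_y), 1 - 2 * (q_y^2 + q_z^2))
  sp <- 2 * (q_w * q_y - q_z * q_x)
  pitch <- asin(pmin(1, pmax(-1, sp)))
  roll <- atan2(2 * (q_w * q_x + q_y * q_z), 1 - 2 * (q_x^2 + q_y^2))
  data.frame(yaw = yaw, pitch = pitch, roll = roll)
}

#' Quaternion from Z-Y-X Euler angles
#'
#' Inverse of [euler_from_quaternion()]: composes yaw (about z), then
#' pitch (about y), then roll (about x).
#'
#' @param yaw,pitch,roll angles in radians (vectors of equal length).
#' @return data.frame with columns `q_w`, `q_x`, `q_y`, `q_z`.
#' @export
quaternion_from_euler <- function(yaw, pitch, roll) {
  cy <- cos(yaw / 2);  sy <- sin(yaw / 2)
  cp <- cos(pitch / 2); sp <- sin(pitch / 2)
  cr <- cos(roll / 2);  sr <- sin(roll / 2)
  data.frame(
    q_w = cr * cp * cy + sr * sp * sy,
    q_x = sr * cp * cy - cr * sp * sy,
    q_y = cr * sp * cy + sr * cp * sy,
    q_z = cr * cp * sy - sr * sp * cy)
}

#' Anatomical-frame series from a sensor stream
#'
#' Bundles the anatomical-frame kinematics used downstream: horizontal
#' speed, ground track, forward acceleration, up-positive vertical
#' velocity and acceleration, and pitch/yaw from the quaternion.
#'
#' @param stream a [sensor_stream()].
#' @param stall_threshold see [compute_ground_track()].
#' @return data.frame of class `anatomical_series` with columns `t`,
#'   `speed`, `track`, `a_forward`, `v_vertical`, `a_vertical`, `pitch`,
#'   `yaw`, `roll`; `rate` attribute carried over.
#' @export
anatomical_series <- function(stream, stall_threshold = 0.3) {
  eul <- euler_from_quaternion(stream$q_w, stream$q_x, stream$q_y,
                               stream$q_z)
  out <- data.frame(
    t = stream$t,
    speed = compute_speed(stream$v_north, stream$v_east),
    track = compute_ground_track(stream$v_north, stream$v_east,
                                 stall_threshold),
    a_forward = compute_forward_acceleration(stream$a_north, stream$a_east),
    v_vertical = vertical_from_ned(stream$v_down),
    a_vertical = stream$a_up,
    pitch = eul$pitch, yaw = eul$yaw, roll = eul$roll)
  structure(out, class = c("anatomical_series", "data.frame"),
            rate = attr(stream, "rate"))
}
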