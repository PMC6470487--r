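# Core time-series containers and delimited-log I/O.
#
# All streams are plain data.frames with a class tag and a "rate" attribute.
# Timestamps are float seconds from an arbitrary (GPS-time-like) origin.

#' Construct a fused INS/GPS sensor stream
#'
#' A `sensor_stream` holds the fused navigation output of a body-mounted
#' INS/GPS at a nominal 400 Hz: NED velocity, horizontal (north/east) and
#' up-positive vertical acceleration, body angular rate, orientation
#' quaternion (body to NED, w-x-y-z) and, optionally, a local position track.
#'
#' @param df data.frame with columns `t`, `v_north`, `v_east`, `v_down`,
#'   `a_north`, `a_east`, `a_up`, `omega_x`, `omega_y`, `omega_z`,
#'   `q_w`, `q_x`, `q_y`, `q_z` and optionally `pos_north`, `pos_east`,
#'   `alt`. Velocities m/s, accelerations m/s^2, angular rates rad/s,
#'   times seconds.
#' @param rate nominal sample rate in Hz.
#' @param validate check the stream invariants (strictly increasing time,
#'   median interval within 1% of `1/rate`, unit quaternions, no missing
#'   values). Gaps are not represented; a gap means two separate streams.
#' @return the data.frame with class `sensor_stream` and a `rate` attribute.
#' @export
sensor_stream <- function(df, rate = 400, validate = TRUE) {
  required <- c("t", "v_north", "v_east", "v_down", "a_north", "a_east",
                "a_up", "omega_x", "omega_y", "omega_z",
                "q_w", "q_x", "q_y", "q_z")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("sensor stream is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- as.data.frame(df)
  if (validate) {
    validate_time_axis(df$t, rate)
    core <- df[, required]
    if (anyNA(core))
      stop("sensor stream contains missing values; gaps must be split into ",
           "separate streams", call. = FALSE)
    qn <- sqrt(df$q_w^2 + df$q_x^2 + df$q_y^2 + df$q_z^2)
    bad <- which(abs(qn - 1) > 1e-6)
    if (length(bad) > 0)
      stop(sprintf("non-unit quaternion at sample %d (|q| = %.9f)",
                   bad[1], qn[bad[1]]), call. = FALSE)
  }
  structure(df, class = c("sensor_stream", "data.frame"), rate = rate)
}

validate_time_axis <- function(t, rate) {
  if (anyNA(t)) stop("missing timestamps", call. = FALSE)
  d <- diff(t)
  bad <- which(d <= 0)
  if (length(bad) > 0)
    stop(sprintf("timestamps not strictly increasing at sample %d (t = %.9g)",
                 bad[1] + 1, t[bad[1] + 1]), call. = FALSE)
  if (length(d) > 0) {
    md <- stats::median(d)
    if (abs(md - 1 / rate) > 0.01 / rate)
      stop(sprintf(paste0("median sample interval %.6g s deviates more than ",
                          "1%% from nominal 1/%g s"), md, rate),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct an instrumented-insole force stream
#'
#' Per-foot total vertical force sampled at the insole's native rate
#' (50 Hz with 13 pressure sensors per insole, 100 Hz with 6).
#'
#' @param t time in seconds.
#' @param force_left,force_right total vertical force per foot, newtons,
#'   non-negative.
#' @param rate sample rate of `t` in Hz.
#' @param native_rate the rate the insole recorded at (kept across
#'   resampling). Must be 50 or 100 for data read from a log.
#' @return data.frame of class `insole_stream` with `rate` and
#'   `native_rate` attributes.
#' @export
insole_stream <- function(t, force_left, force_right, rate,
                          native_rate = rate) {
  if (length(t) != length(force_left) || length(t) != length(force_right))
    stop("t, force_left and force_right must have equal length", call. = FALSE)
  if (any(force_left < 0) || any(force_right < 0))
    stop("insole forces must be non-negative", call. = FALSE)
  validate_time_axis(t, rate)
  structure(data.frame(t = t, force_left = force_left,
                       force_right = force_right),
            class = c("insole_stream", "data.frame"),
            rate = rate, native_rate = native_rate)
}

#' Construct a binary ground-contact series
#'
#' @param t time in seconds (400 Hz grid).
#' @param contact_left,contact_right per-foot contact, exactly 0 or 1.
#' @param rate sample rate in Hz.
#' @return data.frame of class `contact_series`.
#' @export
contact_series <- function(t, contact_left, contact_right, rate = 400) {
  if (!all(contact_left %in% c(0, 1)) || !all(contact_right %in% c(0, 1)))
    stop("contact values must be exactly 0 or 1", call. = FALSE)
  structure(data.frame(t = t, contact_left = as.integer(contact_left),
                       contact_right = as.integer(contact_right)),
            class = c("contact_series", "data.frame"), rate = rate)
}

#' Default column mapping for sensor logs
#'
#' Maps the package's field names to the column headers of a delimited log.
#' Entries may be renamed to match a recorder's headers; the quaternion
#' component order is declared explicitly (default w,x,y,z).
#'
#' @param ... named overrides, e.g. `v_north = "VelN"`.
#' @param quat_order character, one of `"wxyz"` or `"xyzw"`.
#' @return named list mapping internal names to file column names.
#' @export
sensor_dialect <- function(..., quat_order = "wxyz") {
  map <- list(t = "t", v_north = "v_north", v_east = "v_east",
              v_down = "v_down", a_north = "a_north", a_east = "a_east",
              a_up = "a_up", omega_x = "omega_x", omega_y = "omega_y",
              omega_z = "omega_z", q_w = "q_w", q_x = "q_x", q_y = "q_y",
              q_z = "q_z", pos_north = "pos_north", pos_east = "pos_east",
              alt = "alt")
  dots <- list(...)
  map[names(dots)] <- dots
  quat_order <- match.arg(quat_order, c("wxyz", "xyzw"))
  attr(map, "quat_order") <- quat_order
  map
}

#' Read a fused INS/GPS sensor log
#'
#' Reads a delimited text log (CSV with a header row) into a validated
#' [sensor_stream()]. Column names are resolved through a dialect so logs
#' from different recorders can be ingested without rewriting files.
#'
#' @param path path to the CSV file.
#' @param dialect column mapping from [sensor_dialect()].
#' @param rate nominal sample rate, Hz.
#' @return a [sensor_stream()].
#' @export
read_sensor_log <- function(path, dialect = sensor_dialect(), rate = 400) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- data.table::fread(path, data.table = FALSE)
  mandatory <- c("t", "v_north", "v_east", "v_down", "a_north", "a_east",
                 "a_up", "omega_x", "omega_y", "omega_z",
                 "q_w", "q_x", "q_y", "q_z")
  out <- list()
  for (field in names(dialect)) {
    col <- dialect[[field]]
    if (col %in% names(raw)) {
      out[[field]] <- raw[[col]]
    } else if (field %in% mandatory) {
      stop(sprintf("missing mandatory column '%s' (field '%s') in %s",
                   col, field, path), call. = FALSE)
    }
  }
  if (identical(attr(dialect, "quat_order"), "xyzw")) {
    # file stored x,y,z,w under the q_* headers; rotate into w,x,y,z
    qs <- out[c("q_w", "q_x", "q_y", "q_z")]
    out[["q_x"]] <- qs[["q_w"]]; out[["q_y"]] <- qs[["q_x"]]
    out[["q_z"]] <- qs[["q_y"]]; out[["q_w"]] <- qs[["q_z"]]
  }
  sensor_stream(as.data.frame(out), rate = rate)
}

#' Write a sensor stream to CSV
#'
#' Columns are written in a fixed order with full double precision
#' (at least 9 significant digits), so that `read_sensor_log()` recovers
#' the stream to within 1e-9.
#'
#' @param x a [sensor_stream()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sensor_log <- function(x, path) {
  cols <- intersect(c("t", "v_north", "v_east", "v_down", "a_north",
                      "a_east", "a_up", "omega_x", "omega_y", "omega_z",
                      "q_w", "q_x", "q_y", "q_z", "pos_north", "pos_east",
                      "alt"), names(x))
  df <- as.data.frame(x)[, cols]
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read an instrumented-insole force log
#'
#' @param path CSV with columns `t`, `force_left`, `force_right`.
#' @param native_rate the insole output rate, 50 or 100 Hz.
#' @return an [insole_stream()].
#' @export
read_insole_log <- function(path, native_rate = 100) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!native_rate %in% c(50, 100))
    stop("insole native rate must be 50 or 100 Hz", call. = FALSE)
  raw <- data.table::fread(path, data.table = FALSE)
  for (col in c("t", "force_left", "force_right"))
    if (!col %in% names(raw))
      stop(sprintf("missing mandatory column '%s' in %s", col, path),
           call. = FALSE)
  insole_stream(raw$t, raw$force_left, raw$force_right, rate = native_rate)
}

#' Write an insole stream to CSV
#' @param x an [insole_stream()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_insole_log <- function(x, path) {
  data.table::fwrite(as.data.frame(x)[, c("t", "force_left", "force_right")],
                     path)
  invisible(path)
}

#' Resample an insole stream onto a faster grid
#'
#' Linear interpolation onto a uniform grid covering the original span,
#' matching the practice of up-sampling 50/100 Hz insole output to the
#' 400 Hz navigation grid. Endpoints are clamped; forces stay non-negative.
#'
#' @param s an [insole_stream()].
#' @param target_rate target rate in Hz, at least the current rate.
#' @return an [insole_stream()] at `target_rate`.
#' @export
resample_insole <- function(s, target_rate = 400) {
  rate <- attr(s, "rate")
  if (target_rate < rate)
    stop("target_rate must be >= the stream's current rate", call. = FALSE)
  grid <- seq(s$t[1], s$t[nrow(s)], by = 1 / target_rate)
  fl <- stats::approx(s$t, s$force_left, xout = grid, rule = 2)$y
  fr <- stats::approx(s$t, s$force_right, xout = grid, rule = 2)$y
  insole_stream(grid, pmax(fl, 0), pmax(fr, 0), rate = target_rate,
                native_rate = attr(s, "native_rate"))
}

#' Binarize insole forces into a ground-contact series
#'
#' A foot is labelled "on the ground" when its total vertical force exceeds
#' a threshold. The insole binarization threshold is not standardized;
#' 20 N (about 3% of body weight) comfortably clears baseline force noise
#' while catching early/late stance.
#'
#' @param s an [insole_stream()] (any rate).
#' @param force_threshold threshold in newtons, > 0.
#' @return a [contact_series()] on the same grid.
#' @export
binarize_contact <- function(s, force_threshold = 20) {
  if (force_threshold <= 0) stop("force_threshold must be > 0", call. = FALSE)
  contact_series(s$t,
                 as.integer(s$force_left > force_threshold),
                 as.integer(s$force_right > force_threshold),
                 rate = attr(s, "rate"))
}

#' Align a sensor and an insole stream on a common 400 Hz grid
#'
#' Applies a clock offset to the insole stream, crops both streams to the
#' overlapping interval and resamples the insole forces onto the sensor
#' samples inside the overlap.
#'
#' @param sensor a [sensor_stream()].
#' @param insole an [insole_stream()].
#' @param offset seconds added to the insole clock to bring it onto the
#'   sensor clock (estimate with [estimate_sync_offset()]).
#' @return list with elements `sensor` and `insole`, both covering exactly
#'   the overlap on the sensor grid.
#' @export
align_streams <- function(sensor, insole, offset = 0) {
  ti <- insole$t + offset
  lo <- max(sensor$t[1], ti[1])
  hi <- min(sensor$t[nrow(sensor)], ti[length(ti)])
  if (hi <= lo)
    stop("streams do not overlap after applying the offset", call. = FALSE)
  keep <- sensor$t >= lo & sensor$t <= hi
  sen <- sensor_stream(as.data.frame(sensor)[keep, , drop = FALSE],
                       rate = attr(sensor, "rate"), validate = FALSE)
  grid <- sen$t
  fl <- stats::approx(ti, insole$force_left, xout = grid, rule = 2)$y
  fr <- stats::approx(ti, insole$force_right, xout = grid, rule = 2)$y
  ins <- insole_stream(grid, pmax(fl, 0), pmax(fr, 0),
                       rate = attr(sensor, "rate"),
                       native_rate = attr(insole, "native_rate"))
  list(sensor = sen, insole = ins)
}

#' Estimate the insole clock offset by cross-correlation
#'
#' Field recordings are synchronized with deliberate jumps that produce a
#' sharp transient in both the body acceleration and the insole force.
#' The offset is recovered by cross-correlating the high-passed vertical
#' acceleration with the high-passed total force on a common grid.
#'
#' @param sensor a [sensor_stream()].
#' @param insole an [insole_stream()].
#' @param max_lag largest |offset| searched, seconds.
#' @return the offset (seconds) to pass to [align_streams()].
#' @export
estimate_sync_offset <- function(sensor, insole, max_lag = 5) {
  rate <- attr(sensor, "rate")
  ins <- resample_insole(insole, rate)
  ftot <- ins$force_left + ins$force_right
  # common origin: work on sample sequences, then convert lag to seconds
  x <- diff(sensor$a_up)
  y <- diff(ftot)
  x <- x - mean(x); y <- y - mean(y)
  nl <- min(length(x) - 1, length(y) - 1, round(max_lag * rate))
  cc <- stats::ccf(y, x, lag.max = nl, plot = FALSE, demean = FALSE)
  lag <- cc$lag[which.max(abs(cc$acf))]
  # insole events occur `lag` samples later on its own clock relative to the
  # sensor clock start; shifting by the start difference minus the lag
  (sensor$t[1] - ins$t[1]) - lag / rate
}
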