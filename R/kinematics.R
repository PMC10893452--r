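# Kinematic derivations from orientation traces: total angular speed,
# per-axis angular velocity, angular acceleration, head-angle magnitude,
# plus the two smoothing primitives the classifiers rely on.

#' Convert a duration in milliseconds to a sample count
#'
#' @param ms duration in milliseconds.
#' @param rate sample rate in Hz.
#' @param odd force the result odd (rounded up), as required by the
#'   Savitzky-Golay filter.
#' @return integer number of samples, at least 1.
#' @export
ms_to_samples <- function(ms, rate, odd = FALSE) {
  n <- max(1L, as.integer(round(ms * rate / 1000)))
  if (odd && n %% 2L == 0L) n <- n + 1L
  n
}

#' Total angular speed of a trace
#'
#' Geodesic angle between consecutive orientations divided by the sample
#' interval (deg/s). The first sample copies the second so the series keeps
#' the trace's length.
#'
#' @param trace a uniform [head_trace()].
#' @return numeric vector of angular speeds (deg/s), same length as the trace.
#' @export
angular_speed <- function(trace) {
  stopifnot(inherits(trace, "head_trace"))
  n <- length(trace$time)
  if (n < 2L) stop("angular speed needs at least 2 samples")
  q <- quat_align_signs(trace$quat)
  ang <- quat_angle(q[-n, , drop = FALSE], q[-1L, , drop = FALSE])
  dt <- diff(trace$time)
  v <- ang / dt
  c(v[1], v)
}

#' Per-axis angular velocity
#'
#' Default: central finite differences of unwrapped engine Euler angles
#' (pitch about X, yaw about Y, roll about Z), the axis-wise rotation rates
#' an engine reports. Alternatively (`method = "body"`), the body-frame
#' angular velocity vector from quaternion differentiation,
#' omega = 2 q* dq/dt. Endpoints use one-sided differences. Samples with
#' |pitch| > 89 deg are flagged in the gimbal quality mask (Euler rates are
#' unreliable there) but still returned.
#'
#' @param trace a uniform [head_trace()].
#' @param method `"euler"` (default) or `"body"`.
#' @return a list with `vel` (n x 3 matrix, deg/s, columns x, y, z) and
#'   `gimbal` (logical mask of gimbal-proximal samples).
#' @export
per_axis_angular_velocity <- function(trace, method = c("euler", "body")) {
  stopifnot(inherits(trace, "head_trace"))
  method <- match.arg(method)
  n <- length(trace$time)
  if (n < 2L) stop("angular velocity needs at least 2 samples")
  eul <- quat_to_euler(trace$quat)
  gimbal <- abs(eul[, "pitch"]) > 89
  if (method == "euler") {
    unwrapped <- apply(eul, 2, unwrap_deg)
    vel <- apply(unwrapped, 2, central_diff, dt = 1 / trace$rate)
    colnames(vel) <- c("x", "y", "z")
  } else {
    q <- quat_align_signs(trace$quat)
    dq <- apply(q, 2, central_diff, dt = 1 / trace$rate)
    om <- quat_multiply(quat_conjugate(q), dq)  # 0.5 * body angular velocity
    vel <- 2 * om[, 2:4, drop = FALSE] * 180 / pi
    colnames(vel) <- c("x", "y", "z")
  }
  list(vel = vel, gimbal = gimbal)
}

#' Unwrap a periodic angle series (degrees)
#'
#' Removes +/-360 deg jumps so finite differences see a continuous signal.
#'
#' @param x angle series in degrees.
#' @return unwrapped series.
#' @keywords internal
unwrap_deg <- function(x) {
  d <- diff(x)
  d <- d - 360 * round(d / 360)
  c(x[1], x[1] + cumsum(d))
}

#' Central finite difference with one-sided endpoints
#'
#' @param x numeric series.
#' @param dt sample interval (s).
#' @return derivative series of the same length.
#' @keywords internal
central_diff <- function(x, dt) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  if (n > 2L) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d
}

#' Head-angle magnitude
#'
#' Angle (degrees, in [0, 180]) between the head's forward vector and the
#' world forward vector (+Z). Invariant to roll about the forward axis.
#'
#' @param trace a [head_trace()].
#' @return numeric vector of angles in degrees.
#' @export
head_angle_magnitude <- function(trace) {
  stopifnot(inherits(trace, "head_trace"))
  fwd <- quat_rotate(trace$quat, c(0, 0, 1))
  acos(pmax(-1, pmin(1, fwd[, 3]))) * 180 / pi
}

#' Angular acceleration from a speed series
#'
#' Central finite difference of the angular-speed series (deg/s^2), with
#' one-sided differences at the endpoints.
#'
#' @param speed angular-speed series (deg/s).
#' @param dt uniform sample interval (s).
#' @return acceleration series (deg/s^2), same length.
#' @export
angular_acceleration <- function(speed, dt) {
  central_diff(speed, dt)
}

#' Savitzky-Golay smoothing
#'
#' Least-squares local-polynomial smoothing; reproduces polynomials up to
#' `polyorder` exactly, including at the series edges.
#'
#' @param x numeric series.
#' @param window_samples odd window length in samples.
#' @param polyorder polynomial order, less than `window_samples`.
#' @return smoothed series of the same length.
#' @export
savgol_smooth <- function(x, window_samples, polyorder = 3L) {
  window_samples <- as.integer(window_samples)
  if (window_samples %% 2L != 1L) stop("window_samples must be odd")
  if (polyorder >= window_samples) stop("polyorder must be < window_samples")
  if (window_samples > length(x)) stop("window longer than series")
  if (window_samples == 1L) return(x)
  signal::sgolayfilt(x, p = polyorder, n = window_samples)
}

#' Zero-phase low-pass filter
#'
#' Order-2 Butterworth applied forward and backward (4th-order effective
#' attenuation, exactly zero phase), so zero crossings of the filtered
#' signal are not time-shifted.
#'
#' @param x numeric series.
#' @param cutoff cutoff frequency in Hz (must be below Nyquist).
#' @param rate sample rate in Hz.
#' @return filtered series of the same length.
#' @export
lowpass_zero_phase <- function(x, cutoff, rate) {
  if (cutoff >= rate / 2) stop("cutoff must be below the Nyquist frequency")
  if (cutoff <= 0) stop("cutoff must be positive")
  b <- signal::butter(2, cutoff / (rate / 2))
  signal::filtfilt(b, x)
}

#' Derive the full kinematic bundle from a trace
#'
#' Computes every per-sample signal the classifiers consume: total angular
#' speed, Savitzky-Golay smoothed speed, per-axis angular velocity, angular
#' acceleration (derivative of smoothed speed), and head-angle magnitude.
#' All series share the trace's timestamps and length.
#'
#' @param trace a uniform [head_trace()] (resampled first if not).
#' @param savgol_window_ms Savitzky-Golay window for the smoothed speed, in
#'   milliseconds (converted to an odd sample count; default 122 ms, i.e.
#'   11 samples at 90 Hz).
#' @param savgol_polyorder polynomial order of the smoothing filter.
#' @param axis_method per-axis velocity method, see
#'   [per_axis_angular_velocity()].
#' @return an object of class `head_kinematics`: list with `time`, `rate`,
#'   `dt`, `speed`, `speed_smooth`, `accel` (deg/s^2, from smoothed speed),
#'   `vel` (n x 3), `head_angle`, `gimbal`, `markers`, and the source `trace`.
#' @examples
#' tr <- head_trace(seq(0, 1, by = 1/90),
#'                  euler = cbind(0, seq(0, 20, length.out = 91), 0))
#' kin <- head_kinematics(tr)
#' summary(kin$speed)
#' @export
head_kinematics <- function(trace, savgol_window_ms = 122,
                            savgol_polyorder = 3L,
                            axis_method = c("euler", "body")) {
  stopifnot(inherits(trace, "head_trace"))
  if (!trace$uniform) trace <- resample_uniform(trace)
  axis_method <- match.arg(axis_method)
  dt <- 1 / trace$rate
  speed <- angular_speed(trace)
  win <- ms_to_samples(savgol_window_ms, trace$rate, odd = TRUE)
  win <- min(win, if (length(speed) %% 2L == 1L) length(speed) else length(speed) - 1L)
  sm <- savgol_smooth(speed, win, savgol_polyorder)
  ax <- per_axis_angular_velocity(trace, axis_method)
  structure(list(time = trace$time, rate = trace$rate, dt = dt,
                 speed = speed, speed_smooth = sm,
                 accel = angular_acceleration(sm, dt),
                 vel = ax$vel, gimbal = ax$gimbal,
                 head_angle = head_angle_magnitude(trace),
                 markers = trace$markers, trace = trace),
            class = "head_kinematics")
}

#' @export
print.head_kinematics <- function(x, ...) {
  cat(sprintf("<head_kinematics> %d samples at %.1f Hz; speed %.2f-%.2f deg/s, head angle %.2f-%.2f deg\n",
              length(x$time), x$rate, min(x$speed), max(x$speed),
              min(x$head_angle), max(x$head_angle)))
  invisible(x)
}

#' Plot kinematic series with optional classified events
#'
#' Draws angular speed and head-angle magnitude over time; classified
#' movement windows, if supplied, are shaded.
#'
#' @param x a `head_kinematics` object.
#' @param events optional [head_events()] to overlay.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.head_kinematics <- function(x, events = NULL, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$time, x$speed, type = "l", col = "grey50",
                 xlab = "time (s)", ylab = "angular speed (deg/s)", ...)
  graphics::lines(x$time, x$speed_smooth, col = "purple")
  if (!is.null(events) && nrow(events)) {
    usr <- graphics::par("usr")
    graphics::rect(events$onset, usr[3], events$offset, usr[4],
                   col = grDevices::adjustcolor("red", 0.15), border = NA)
  }
  graphics::plot(x$time, x$head_angle, type = "l",
                 xlab = "time (s)", ylab = "head angle (deg)")
  invisible(x)
}
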