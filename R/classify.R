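# The rule-based head-movement classifiers: baseline-adaptive elliptic
# threshold (BMAT), smoothed velocity threshold with acceleration-zero
# boundary search (SVT), the sliding-window percentage rule of Chen & Walton,
# and the acceleration zero-crossing direction coder (DIZCO).

#' Extract baseline per-axis velocities from pre-trial windows
#'
#' Collects the per-axis angular velocities in the stationary window
#' preceding each `trial_start` marker (participants fixate a central disk
#' there, so the head is nominally still). These samples parameterize the
#' baseline noise ellipse of [classify_bmat()] and the default rest
#' threshold of [classify_dizco()].
#'
#' @param kin a [head_kinematics()] with trial markers.
#' @param window_ms baseline window length before each trial start (ms).
#' @return matrix of baseline per-axis velocities (columns x, y, z).
#' @export
baseline_velocities <- function(kin, window_ms = 500) {
  stopifnot(inherits(kin, "head_kinematics"))
  mk <- kin$markers
  if (is.null(mk) || !any(mk$kind == "trial_start")) {
    stop("no trial_start markers: supply an explicit baseline instead")
  }
  starts <- mk$time[mk$kind == "trial_start"]
  sel <- rep(FALSE, length(kin$time))
  for (s in starts) {
    sel <- sel | (kin$time >= s - window_ms / 1000 & kin$time < s)
  }
  kin$vel[sel, , drop = FALSE]
}

#' Baseline-adaptive elliptic velocity threshold (BMAT)
#'
#' An adaptation of the elliptic velocity-threshold idea from microsaccade
#' detection: a 3-D ellipsoid is placed at the mean of the baseline per-axis
#' angular velocities with semi-axes `n_sd` baseline standard deviations,
#' and a sample is labeled moving when its velocity vector falls outside the
#' ellipsoid, i.e. when
#' \deqn{\sum_{a \in \{x,y,z\}} \left(\frac{v_a - \mu_a}{n \sigma_a}\right)^2 > 1.}
#' Axis standard deviations are floored at 1e-6 deg/s; a baseline with zero
#' variance on every axis is rejected.
#'
#' @param kin a [head_kinematics()].
#' @param baseline matrix of baseline per-axis velocities (n x 3); default:
#'   extracted from the pre-trial windows via [baseline_velocities()].
#' @param config a [bmat_config()].
#' @return a [label_series()] over the kinematic timestamps.
#' @references Engbert & Kliegl (2003), Vision Research 43, 1035-1045.
#' @export
classify_bmat <- function(kin, baseline = NULL, config = bmat_config()) {
  stopifnot(inherits(kin, "head_kinematics"), inherits(config, "bmat_config"))
  if (is.null(baseline)) {
    baseline <- baseline_velocities(kin, config$baseline_window_ms)
  }
  baseline <- as.matrix(baseline)
  if (nrow(baseline) < 10L) stop("baseline needs at least 10 samples per axis")
  if (config$robust) {
    mu <- apply(baseline, 2, stats::median)
    sig <- sqrt(pmax(0, apply(baseline^2, 2, stats::median) - mu^2))
  } else {
    mu <- colMeans(baseline)
    sig <- apply(baseline, 2, stats::sd)
  }
  if (all(sig < 1e-12)) {
    stop("baseline has zero variance on all axes; cannot form a velocity ellipse")
  }
  sig <- pmax(sig, 1e-6)
  r2 <- sweep(sweep(kin$vel, 2, mu), 2, config$n_sd * sig, "/")^2
  label_series(kin$time, rowSums(r2) > 1)
}

#' Find local maxima of a series
#' @keywords internal
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer())
  which(x[2:(n - 1)] >= x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
}

#' Smoothed velocity threshold classifier (SVT)
#'
#' Angular speed is smoothed with a Savitzky-Golay filter; every local
#' maximum of the smoothed speed above `speed_threshold` seeds an event.
#' From each seeding peak the algorithm walks backward and forward in time
#' and places the movement onset/offset at the nearest sample where the
#' angular acceleration crosses zero — a sign change, or magnitude below
#' `accel_tol` at plateaus. A zero crossing only terminates the walk once
#' the smoothed speed has dropped back below the threshold, so the
#' acceleration sign flip at the speed peak itself (and the near-zero
#' acceleration along a pursuit plateau) cannot truncate an event. The walk
#' differences the smoothed speed with the same backward convention as the
#' speed series itself (each sample describes the step ending at it), so
#' boundary zero crossings align with the speed support rather than
#' lagging it. The offset zero-crossing sample is the first stationary
#' sample and forms the exclusive bound of the half-open event window;
#' events that overlap or share a boundary are merged.
#'
#' @param kin a [head_kinematics()].
#' @param config an [svt_config()].
#' @return a [head_events()] table (possibly empty).
#' @export
classify_svt <- function(kin, config = svt_config()) {
  stopifnot(inherits(kin, "head_kinematics"), inherits(config, "svt_config"))
  n <- length(kin$time)
  win <- ms_to_samples(config$savgol_window_ms, kin$rate, odd = TRUE)
  win <- min(win, if (n %% 2L == 1L) n else n - 1L)
  sm <- savgol_smooth(kin$speed, win, config$savgol_polyorder)
  a <- c(0, diff(sm)) / kin$dt   # backward difference, matching the speed series
  thr <- config$speed_threshold
  tol <- config$accel_tol
  peaks <- local_maxima(sm)
  peaks <- peaks[sm[peaks] > thr]
  if (!length(peaks)) return(head_events())
  onsets <- integer(length(peaks))
  offsets <- integer(length(peaks))
  prev_off <- 1L
  for (k in seq_along(peaks)) {
    p <- peaks[k]
    i <- p
    while (i > prev_off && (sm[i] > thr || a[i] > tol)) i <- i - 1L
    onsets[k] <- max(i, 1L)
    j <- p
    while (j < n && (sm[j] > thr || a[min(j + 1L, n)] < -tol)) j <- j + 1L
    offsets[k] <- min(j, n)
    prev_off <- offsets[k]
  }
  # merge events that overlap or share a boundary sample
  out_on <- integer()
  out_off <- integer()
  cur_on <- onsets[1]; cur_off <- offsets[1]
  for (k in seq_along(peaks)[-1]) {
    if (onsets[k] <= cur_off) {
      cur_off <- max(cur_off, offsets[k])
    } else {
      out_on <- c(out_on, cur_on); out_off <- c(out_off, cur_off)
      cur_on <- onsets[k]; cur_off <- offsets[k]
    }
  }
  out_on <- c(out_on, cur_on); out_off <- c(out_off, cur_off)
  head_events(onset = kin$time[out_on], offset = kin$time[out_off])
}

#' Sliding-window percentage-rule classifier (Chen & Walton)
#'
#' Adapted from a macaque head-movement segmentation rule. A sliding onset
#' window (100 ms) scans the angular-speed series; a window qualifies when
#' at least `ceiling(frac * window)` of its samples are above
#' `speed_threshold` and it contains no run of `max_consecutive_below` or
#' more consecutive below-threshold samples. Movement onset is the first
#' above-threshold sample of the first qualifying window. The scan then
#' switches to offset mode with a 22 ms window requiring
#' `ceiling(frac * window)` samples below threshold; offset is the first
#' below-threshold sample of the qualifying window. Modes alternate to the
#' end of the series.
#'
#' @param kin a [head_kinematics()], or a bare numeric speed series if
#'   `rate` is given.
#' @param config a [cw_config()].
#' @param rate sample rate in Hz (only needed for a bare speed series).
#' @return a [head_events()] table.
#' @references Chen & Walton (2005), J Neurophysiol 94, 4502-4519.
#' @export
classify_cw <- function(kin, config = cw_config(), rate = NULL) {
  stopifnot(inherits(config, "cw_config"))
  if (inherits(kin, "head_kinematics")) {
    speed <- kin$speed
    rate <- kin$rate
    time <- kin$time
  } else {
    speed <- as.numeric(kin)
    if (is.null(rate)) stop("rate is required for a bare speed series")
    time <- (seq_along(speed) - 1) / rate
  }
  n <- length(speed)
  won <- ms_to_samples(config$onset_window_ms, rate)
  woff <- ms_to_samples(config$offset_window_ms, rate)
  if (n < won) return(head_events())
  kon <- ceiling(config$frac * won)
  koff <- ceiling(config$frac * woff)
  maxcb <- config$max_consecutive_below
  above <- speed > config$speed_threshold
  below <- !above

  n_on <- n - won + 1L
  count_above <- cumsum_window(above, won)
  # windows containing a run of >= maxcb consecutive below-threshold samples
  run_start <- rep(FALSE, n)
  if (n >= maxcb) {
    rs <- rep(TRUE, n - maxcb + 1L)
    for (o in 0:(maxcb - 1L)) rs <- rs & below[(1L + o):(n - maxcb + 1L + o)]
    run_start[seq_along(rs)] <- rs
  }
  has_run <- cumsum_window(run_start, won - maxcb + 1L) > 0
  q_on <- count_above >= kon & !has_run[seq_len(n_on)]

  n_off <- n - woff + 1L
  q_off <- cumsum_window(below, woff) >= koff

  onsets <- integer(); offsets <- integer()
  s <- 1L
  repeat {
    # onset mode
    w <- which(q_on[s:n_on])
    if (!length(w)) break
    ws <- s + w[1] - 1L
    onset <- ws - 1L + which(above[ws:(ws + won - 1L)])[1]
    # offset mode
    s2 <- onset + 1L
    offset <- NA_integer_
    if (s2 <= n_off) {
      w2 <- which(q_off[s2:n_off])
      if (length(w2)) {
        ws2 <- s2 + w2[1] - 1L
        offset <- ws2 - 1L + which(below[ws2:(ws2 + woff - 1L)])[1]
      }
    }
    if (is.na(offset)) {
      onsets <- c(onsets, onset); offsets <- c(offsets, n + 1L)
      break
    }
    onsets <- c(onsets, onset); offsets <- c(offsets, offset)
    s <- offset
    if (s > n_on) break
  }
  if (!length(onsets)) return(head_events())
  dt <- 1 / rate
  off_t <- ifelse(offsets > n, time[n] + dt, time[pmin(offsets, n)])
  head_events(onset = time[onsets], offset = off_t)
}

#' Sliding-window sums via cumulative sums
#' @keywords internal
cumsum_window <- function(x, w) {
  n <- length(x)
  if (w > n) return(numeric(0))
  cs <- cumsum(as.numeric(x))
  cs[w:n] - c(0, cs[seq_len(n - w)])
}

#' Acceleration zero-crossing direction coder (DIZCO)
#'
#' Computes the angular accelerations of the horizontal (yaw, left/right)
#' and vertical (pitch, up/down) rotation channels, low-passes both below
#' `cutoff_hz` with a zero-phase filter, and segments the recording at the
#' zero crossings of either filtered series. Within a segment each channel
#' is assigned a state: 0 (resting) when the segment's mean filtered
#' acceleration magnitude on that channel is below the threshold (no
#' appreciable change in instantaneous velocity), otherwise the sign of the
#' channel's rotation slope — the segment's mean filtered angular velocity.
#' The state pair maps to one of the eight compass directions (horizontal
#' + = E, vertical + = N) or to rest when both channels are 0; consecutive
#' segments with the same non-rest direction merge into one movement event
#' (an orienting movement's accelerating and decelerating halves share a
#' velocity sign, so they fuse into one directed event).
#'
#' If no threshold is configured it defaults to the 95th percentile of the
#' filtered acceleration magnitude during the pre-trial rest windows (the
#' recording's own noise floor); this requires trial markers.
#'
#' @param kin a [head_kinematics()].
#' @param config a [dizco_config()].
#' @return a [head_events()] table with compass `direction` labels.
#' @export
classify_dizco <- function(kin, config = dizco_config()) {
  stopifnot(inherits(kin, "head_kinematics"), inherits(config, "dizco_config"))
  n <- length(kin$time)
  vh <- kin$vel[, "y"]    # yaw rate: + = rightward
  vv <- -kin$vel[, "x"]   # pitch rate, negated so + = upward
  fx <- lowpass_zero_phase(central_diff(vh, kin$dt), config$cutoff_hz, kin$rate)
  fy <- lowpass_zero_phase(central_diff(vv, kin$dt), config$cutoff_hz, kin$rate)
  fvh <- lowpass_zero_phase(vh, config$cutoff_hz, kin$rate)
  fvv <- lowpass_zero_phase(vv, config$cutoff_hz, kin$rate)
  thr <- config$accel_magnitude_threshold
  if (is.null(thr)) {
    mk <- kin$markers
    if (is.null(mk) || !any(mk$kind == "trial_start")) {
      stop("no accel_magnitude_threshold configured and no trial markers to derive one")
    }
    rest <- rep(FALSE, n)
    for (s in mk$time[mk$kind == "trial_start"]) {
      rest <- rest | (kin$time >= s - 0.5 & kin$time < s)
    }
    thr <- stats::quantile(abs(c(fx[rest], fy[rest])), 0.95, names = FALSE)
    if (!is.finite(thr) || thr <= 0) thr <- 1e-6
  }
  sgn <- function(v) v >= 0
  cross <- which(sgn(fx[-1]) != sgn(fx[-n]) | sgn(fy[-1]) != sgn(fy[-n])) + 1L
  bounds <- unique(c(1L, cross, n + 1L))
  k <- length(bounds) - 1L
  seg_dir <- character(k)
  for (i in seq_len(k)) {
    idx <- bounds[i]:(bounds[i + 1L] - 1L)
    sx <- segment_state(fx[idx], fvh[idx], thr)
    sy <- segment_state(fy[idx], fvv[idx], thr)
    seg_dir[i] <- compass_label(sx, sy)
  }
  # bridge momentary sub-threshold slivers: the 1-2 sample segment that sits
  # exactly at a movement's acceleration zero crossing has near-zero mean
  # acceleration magnitude and would otherwise split one movement in two
  r0 <- rle(seg_dir)
  if (length(r0$values) >= 3L) {
    ends0 <- cumsum(r0$lengths)
    starts0 <- ends0 - r0$lengths + 1L
    bridge <- ceiling(0.05 * kin$rate)   # 50 ms
    for (i in 2:(length(r0$values) - 1L)) {
      if (r0$values[i] == "rest" &&
          r0$values[i - 1L] == r0$values[i + 1L] &&
          r0$values[i - 1L] != "rest") {
        n_samp <- bounds[ends0[i] + 1L] - bounds[starts0[i]]
        if (n_samp <= bridge) {
          seg_dir[starts0[i]:ends0[i]] <- r0$values[i - 1L]
        }
      }
    }
  }
  # merge consecutive segments with identical direction
  r <- rle(seg_dir)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "rest"
  if (!any(keep)) return(head_events())
  on_idx <- bounds[starts[keep]]
  off_idx <- bounds[ends[keep] + 1L]
  off_t <- ifelse(off_idx > n, kin$time[n] + kin$dt, kin$time[pmin(off_idx, n)])
  head_events(onset = kin$time[on_idx], offset = off_t,
              direction = r$values[keep])
}

#' @keywords internal
segment_state <- function(a, v, thr) {
  if (mean(abs(a)) < thr) 0L else if (mean(v) >= 0) 1L else -1L
}

#' @keywords internal
compass_label <- function(sx, sy) {
  if (sx == 0L && sy == 0L) return("rest")
  ang <- atan2(sy, sx) * 180 / pi
  idx <- (round(ang / 45) %% 8) + 1L
  .compass[idx]
}
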