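# Fixture builders and independent oracles shared across the suite.
# Everything is generated in code; no stored data.

# trace rotating about the yaw (up) axis at a constant rate
constant_yaw_trace <- function(rate_deg_s = 20, duration = 2, hz = 90) {
  t <- seq(0, duration, by = 1 / hz)
  head_trace(t, euler = cbind(0, rate_deg_s * t, 0))
}

# trace whose angular speed is a raised-cosine bump: peak `vp` deg/s over
# support `dur` s (amplitude vp * dur / 2), padded with rest on both sides
bump_trace <- function(vp = 30, dur = 0.5, pad = 1, hz = 90,
                       axis = c(0, 1, 0)) {
  t <- seq(0, dur + 2 * pad, by = 1 / hz)
  amp <- vp * dur / 2
  u <- (t - pad) / dur
  prog <- ifelse(u <= 0, 0, ifelse(u >= 1, 1, u - sin(2 * pi * u) / (2 * pi)))
  theta <- amp * prog
  half <- theta * pi / 360
  q <- cbind(cos(half), sin(half) %o% (axis / sqrt(sum(axis^2))))
  list(trace = head_trace(t, quat = q), onset = pad, offset = pad + dur,
       amplitude = amp, vp = vp)
}

# minimal kinematics object wrapping an explicit per-axis velocity matrix,
# for classifier tests that do not need a full trace behind it
kin_from_vel <- function(vel, hz = 90) {
  n <- nrow(vel)
  structure(list(time = (seq_len(n) - 1) / hz, rate = hz, dt = 1 / hz,
                 speed = sqrt(rowSums(vel^2)),
                 speed_smooth = sqrt(rowSums(vel^2)),
                 accel = rep(0, n), vel = vel,
                 gimbal = rep(FALSE, n),
                 head_angle = rep(0, n), markers = NULL, trace = NULL),
            class = "head_kinematics")
}

# brute-force Cohen's kappa from an explicitly tabulated 2x2 contingency
oracle_kappa <- function(x, y) {
  x <- factor(as.integer(x), levels = 0:1)
  y <- factor(as.integer(y), levels = 0:1)
  tab <- table(x, y) / length(x)
  po <- tab[1, 1] + tab[2, 2]
  pe <- sum(rowSums(tab) * colSums(tab))
  (po - pe) / (1 - pe)
}

# literal re-scan of the Chen & Walton window rules: every window position
# is qualified independently (rle-based run check), then the onset/offset
# alternation is walked over the qualification vectors
oracle_cw <- function(speed, rate, cfg) {
  n <- length(speed)
  won <- max(1L, round(cfg$onset_window_ms * rate / 1000))
  woff <- max(1L, round(cfg$offset_window_ms * rate / 1000))
  if (n < won) return(data.frame(onset = numeric(), offset = numeric()))
  above <- speed > cfg$speed_threshold
  q_on <- vapply(seq_len(n - won + 1L), function(s) {
    w <- above[s:(s + won - 1L)]
    runs <- rle(!w)
    sum(w) >= ceiling(cfg$frac * won) &&
      !any(runs$values & runs$lengths >= cfg$max_consecutive_below)
  }, logical(1))
  q_off <- vapply(seq_len(n - woff + 1L), function(s) {
    sum(!above[s:(s + woff - 1L)]) >= ceiling(cfg$frac * woff)
  }, logical(1))
  onsets <- offsets <- integer()
  s <- 1L
  repeat {
    w <- which(q_on[s:length(q_on)])
    if (!length(w)) break
    ws <- s + w[1] - 1L
    onset <- ws - 1L + which(above[ws:(ws + won - 1L)])[1]
    s2 <- onset + 1L
    offset <- NA_integer_
    if (s2 <= length(q_off)) {
      w2 <- which(q_off[s2:length(q_off)])
      if (length(w2)) {
        ws2 <- s2 + w2[1] - 1L
        offset <- ws2 - 1L + which(!above[ws2:(ws2 + woff - 1L)])[1]
      }
    }
    if (is.na(offset)) {
      onsets <- c(onsets, onset); offsets <- c(offsets, n + 1L); break
    }
    onsets <- c(onsets, onset); offsets <- c(offsets, offset)
    s <- offset
    if (s > length(q_on)) break
  }
  time <- (seq_len(n) - 1) / rate
  dt <- 1 / rate
  data.frame(onset = time[onsets],
             offset = ifelse(offsets > n, time[n] + dt,
                             time[pmin(offsets, n)]))
}

expect_events_equal <- function(a, b, tol = 1e-9) {
  expect_equal(nrow(a), nrow(b))
  if (nrow(a)) {
    expect_equal(a$onset, b$onset, tolerance = tol)
    expect_equal(a$offset, b$offset, tolerance = tol)
  }
}
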