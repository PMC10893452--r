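# Seeded simulator of HMD head-rotation recordings with ground-truth
# movement events and synthetic raters. The generative model mirrors a
# target-orienting paradigm: each trial holds a stationary fixation period,
# then a target appears (instantly, or moving smoothly at the pursuit
# speed) at a random eccentricity in one of eight compass directions; the
# head makes one orienting movement toward it, holds, and re-centers after
# the response.

#' Simulator configuration
#'
#' @param rate sample rate in Hz (the HMD refresh rate).
#' @param n_trials trials per recording.
#' @param condition `"instant"` (ballistic orienting movements with a
#'   raised-cosine speed profile) or `"pursuit"` (near-constant-speed
#'   tracking at `pursuit_speed` with smooth ramps).
#' @param eccentricities candidate target eccentricities (deg).
#' @param directions candidate target directions (deg; 0 = E,
#'   counter-clockwise).
#' @param pursuit_speed target (and head) speed in the pursuit condition
#'   (deg/s).
#' @param head_gain fraction of target eccentricity covered by the head
#'   (heads under-rotate relative to gaze; 0.6 by default).
#' @param main_sequence_slope peak velocity per unit amplitude for
#'   ballistic movements ((deg/s)/deg); peak velocity =
#'   slope * amplitude * exp(N(0, peak_vel_noise_sd)).
#' @param peak_vel_noise_sd SD of the log-normal peak-velocity noise.
#' @param noise_sd_deg SD of the band-limited orientation jitter (deg) on
#'   each axis; 0 for noise-free traces.
#' @param noise_cutoff_hz bandwidth of the orientation jitter.
#' @param corrective_prob probability of appending a small (<= 5 deg)
#'   secondary corrective movement after the main one.
#' @param wobble_per_trial number of small unlabeled postural adjustments
#'   inserted during the hold period of each trial. Their peak speeds are
#'   drawn uniformly from `wobble_peak_range`, whose upper edge acts as the
#'   recording's effective velocity boundary between unlabeled drift and
#'   labeled movements.
#' @param wobble_peak_range range of wobble peak speeds (deg/s).
#' @param n_raters number of simulated raters.
#' @param rater_jitter_sd_ms SD of the Gaussian jitter on rated event
#'   boundaries (ms).
#' @param rater_miss_prob probability a rater misses an event entirely.
#' @param rater_onset_shift_ms,rater_offset_shift_ms deterministic boundary
#'   shifts applied by every rater (ms); used to exercise the bias
#'   pipeline.
#' @param seed integer seed; all randomness flows from it through
#'   per-trial substreams.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(rate = 90, n_trials = 16,
                       condition = c("instant", "pursuit"),
                       eccentricities = c(10, 20, 30, 40, 50),
                       directions = seq(0, 315, by = 45),
                       pursuit_speed = 20, head_gain = 0.6,
                       main_sequence_slope = 5, peak_vel_noise_sd = 0.1,
                       noise_sd_deg = 0.02, noise_cutoff_hz = 6,
                       corrective_prob = 0, wobble_per_trial = 0,
                       wobble_peak_range = c(3, 10), n_raters = 2,
                       rater_jitter_sd_ms = 12, rater_miss_prob = 0.02,
                       rater_onset_shift_ms = 0, rater_offset_shift_ms = 0,
                       seed = 1L) {
  condition <- match.arg(condition)
  stopifnot(rate > 0, n_trials >= 1, length(eccentricities) >= 1,
            length(directions) >= 1, noise_sd_deg >= 0,
            rater_jitter_sd_ms >= 0, rater_miss_prob >= 0,
            rater_miss_prob <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Derive a bounded substream seed
#' @keywords internal
substream_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream) * 16807 + 11) %%
               2147483629)
}

# raised-cosine cumulative progress: fraction of distance covered at
# phase u in [0, 1] of a movement whose speed is (1 - cos(2 pi u)) shaped
.rc_progress <- function(u) u - sin(2 * pi * u) / (2 * pi)

#' Simulate one head-rotation recording
#'
#' Produces a uniform orientation trace with trial markers, the exact
#' ground-truth movement events (onset/offset at the speed-profile support,
#' compass direction, amplitude, construction peak velocity), and simulated
#' rater labelings. Identical seeds give bit-identical output.
#'
#' Trial timeline: 500 ms pre-trial rest (the BMAT baseline window),
#' `trial_start`, 500 ms fixation, `target_on`, a reaction latency, the
#' orienting movement (plus optional corrective movement), a hold period
#' (with optional postural wobbles), `response`, and a ballistic
#' re-centering movement. Orienting, corrective and re-centering movements
#' are ground-truth events; wobbles are not.
#'
#' @param cfg a [sim_config()].
#' @return an object of class `hm_sim`: list with `trace` ([head_trace()]),
#'   `truth_events` ([head_events()]), `rater_labels` (list of
#'   [label_series()] masked to trial windows), `trials` (per-trial data
#'   frame), `cfg`.
#' @examples
#' sim <- simulate_trace(sim_config(n_trials = 2, seed = 42))
#' sim$truth_events
#' @export
simulate_trace <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  dt <- 1 / cfg$rate
  seg_time <- list(); seg_theta <- list(); seg_axis <- list()
  markers <- list(); events <- list(); trials <- list()
  t_cur <- 0

  for (tr in seq_len(cfg$n_trials)) {
    set.seed(substream_seed(cfg$seed, tr))
    ecc <- cfg$eccentricities[sample.int(length(cfg$eccentricities), 1)]
    dir_deg <- cfg$directions[sample.int(length(cfg$directions), 1)]
    A <- cfg$head_gain * ecc
    latency <- 0.15 + stats::runif(1, 0, 0.05)
    if (cfg$condition == "instant") {
      vp <- cfg$main_sequence_slope * A *
        exp(stats::rnorm(1, 0, cfg$peak_vel_noise_sd))
      D <- 2 * A / vp
    } else {
      vp <- cfg$pursuit_speed
      ramp <- 0.15
      D <- A / vp + ramp
    }
    corrective <- cfg$corrective_prob > 0 &&
      stats::runif(1) < cfg$corrective_prob
    c_amp <- if (corrective) stats::runif(1, 1, 5) else 0
    c_vp <- if (corrective) cfg$main_sequence_slope * c_amp else 0
    c_D <- if (corrective) 2 * c_amp / c_vp else 0
    hold <- 0.45
    wob <- if (cfg$wobble_per_trial > 0)
      stats::runif(cfg$wobble_per_trial, cfg$wobble_peak_range[1],
                   cfg$wobble_peak_range[2]) else numeric()
    ret_A <- A - c_amp
    ret_vp <- cfg$main_sequence_slope * ret_A
    ret_D <- 2 * ret_A / ret_vp
    if (D > 4 || ret_D > 4) {
      stop("movement longer than the trial window; adjust the configuration")
    }

    # assemble the trial's geodesic progress profile theta(t) on the local grid
    pre <- 0.5; fix <- 0.5
    t_ts <- t_cur + pre                      # trial_start
    t_to <- t_ts + fix                       # target_on
    t_m0 <- t_to + latency                   # movement onset
    t_m1 <- t_m0 + D
    t_c1 <- t_m1 + c_D
    t_h1 <- t_c1 + hold                      # response at end of hold
    t_r0 <- t_h1
    t_r1 <- t_r0 + ret_D
    t_end <- t_r1 + 0.35
    # snap the trial end to the global sample grid so the concatenated
    # trace stays exactly uniform
    n_samp <- round((t_end - t_cur) / dt)
    t_end <- t_cur + n_samp * dt
    tt <- t_cur + (seq_len(n_samp) - 1L) * dt
    th <- numeric(length(tt))
    inm <- tt >= t_m0 & tt < t_m1
    if (cfg$condition == "instant") {
      th[inm] <- A * .rc_progress((tt[inm] - t_m0) / D)
    } else {
      # cosine on/off ramps around a constant-speed plateau
      u <- tt[inm] - t_m0
      v_int <- pursuit_progress(u, vp, D, ramp)
      th[inm] <- pmin(A, v_int)
    }
    th[tt >= t_m1] <- A
    if (corrective) {
      inc <- tt >= t_m1 & tt < t_c1
      th[inc] <- A - c_amp * .rc_progress((tt[inc] - t_m1) / c_D)
      th[tt >= t_c1] <- ret_A
    }
    # wobbles: out-and-back bumps during the hold period, peak speed vw
    if (length(wob)) {
      slots <- seq_len(length(wob))
      for (wi in slots) {
        w_D <- 0.3
        a_w <- wob[wi] * w_D / pi
        w0 <- t_c1 + 0.05 + (wi - 1) * (w_D + 0.02)
        if (w0 + w_D > t_h1 - 0.02) next
        inw <- tt >= w0 & tt < w0 + w_D
        uu <- (tt[inw] - w0) / w_D
        th[inw] <- th[inw] + a_w / 2 * (1 - cos(2 * pi * uu))
      }
    }
    inr <- tt >= t_r0 & tt < t_r1
    base_r <- if (corrective) ret_A else A
    th[inr] <- base_r * (1 - .rc_progress((tt[inr] - t_r0) / ret_D))
    th[tt >= t_r1] <- 0

    dir_rad <- dir_deg * pi / 180
    axis <- c(-sin(dir_rad), cos(dir_rad), 0)
    seg_time[[tr]] <- tt
    seg_theta[[tr]] <- th
    seg_axis[[tr]] <- axis
    markers[[tr]] <- data.frame(
      time = c(t_ts, t_to, t_h1),
      kind = c("trial_start", "target_on", "response"))
    ev <- data.frame(onset = t_m0, offset = t_m1,
                     direction = compass_from_deg(dir_deg),
                     amplitude = A, peak_velocity = vp, trial = tr)
    if (corrective) {
      ev <- rbind(ev, data.frame(onset = t_m1, offset = t_c1,
                                 direction = compass_from_deg(dir_deg + 180),
                                 amplitude = c_amp, peak_velocity = c_vp,
                                 trial = tr))
    }
    ev <- rbind(ev, data.frame(onset = t_r0, offset = t_r1,
                               direction = compass_from_deg(dir_deg + 180),
                               amplitude = base_r, peak_velocity = ret_vp,
                               trial = tr))
    events[[tr]] <- ev
    trials[[tr]] <- data.frame(trial = tr, condition = cfg$condition,
                               eccentricity = ecc, direction_deg = dir_deg,
                               amplitude = A, trial_start = t_ts,
                               target_on = t_to, response = t_h1)
    t_cur <- t_end
  }

  time <- do.call(c, seg_time)
  n <- length(time)
  time <- (seq_len(n) - 1L) * dt   # exact uniform grid, no accumulation error
  quat <- matrix(0, n, 4)
  pos <- 1L
  for (tr in seq_len(cfg$n_trials)) {
    m <- length(seg_time[[tr]])
    idx <- pos:(pos + m - 1L)
    ax <- seg_axis[[tr]]
    half <- seg_theta[[tr]] * pi / 360
    quat[idx, ] <- cbind(cos(half), sin(half) %o% ax)
    pos <- pos + m
  }
  if (cfg$noise_sd_deg > 0) {
    set.seed(substream_seed(cfg$seed, 0L))
    noise <- matrix(stats::rnorm(3 * n), n, 3)
    for (j in 1:3) {
      f <- lowpass_zero_phase(noise[, j], cfg$noise_cutoff_hz, cfg$rate)
      noise[, j] <- f / stats::sd(f) * cfg$noise_sd_deg
    }
    quat <- quat_multiply(quat, euler_to_quat(noise))
  }
  mk <- do.call(rbind, markers)
  trace <- head_trace(time, quat = quat, markers = mk, rate = cfg$rate)
  ev <- do.call(rbind, events)
  truth <- head_events(onset = ev$onset, offset = ev$offset,
                       direction = ev$direction, amplitude = ev$amplitude,
                       peak_velocity = ev$peak_velocity, trial = ev$trial)
  raters <- simulate_raters(truth, time, cfg)
  mask <- trial_mask(time, mk)
  raters <- lapply(raters, function(r) label_series(r$time, r$moving, mask))
  structure(list(trace = trace, truth_events = truth,
                 rater_labels = raters,
                 trials = do.call(rbind, trials), cfg = cfg),
            class = "hm_sim")
}

#' @keywords internal
pursuit_progress <- function(u, vp, D, ramp) {
  # distance covered by a plateau profile with cosine ramps of length `ramp`
  d <- numeric(length(u))
  r1 <- u < ramp
  d[r1] <- vp / 2 * (u[r1] - ramp / pi * sin(pi * u[r1] / ramp))
  mid <- u >= ramp & u < D - ramp
  d[mid] <- vp * ramp / 2 + vp * (u[mid] - ramp)
  r2 <- u >= D - ramp
  ur <- pmin(u[r2] - (D - ramp), ramp)
  d[r2] <- vp * ramp / 2 + vp * (D - 2 * ramp) +
    vp / 2 * (ur + ramp / pi * sin(pi * ur / ramp))
  d
}

#' @keywords internal
compass_from_deg <- function(deg) {
  .compass[(round((deg %% 360) / 45) %% 8) + 1L]
}

#' @export
print.hm_sim <- function(x, ...) {
  cat(sprintf("<hm_sim> %s condition: %d trials, %d samples, %d truth events, %d raters\n",
              x$cfg$condition, x$cfg$n_trials, length(x$trace$time),
              nrow(x$truth_events), length(x$rater_labels)))
  invisible(x)
}

#' Simulate rater labelings of ground-truth events
#'
#' Each rater reproduces the truth events with Gaussian jitter on onset and
#' offset (plus any deterministic shift), drops each event with the miss
#' probability, and is converted to per-sample labels. Offsets are clamped
#' to stay at least two samples after onsets.
#'
#' @param truth a [head_events()] table.
#' @param time sample timestamps to label.
#' @param cfg a [sim_config()] (fields `n_raters`, `rater_jitter_sd_ms`,
#'   `rater_miss_prob`, `rater_onset_shift_ms`, `rater_offset_shift_ms`,
#'   `rate`, `seed`).
#' @return list of [label_series()], one per rater.
#' @export
simulate_raters <- function(truth, time, cfg) {
  dt <- 1 / cfg$rate
  out <- vector("list", cfg$n_raters)
  for (r in seq_len(cfg$n_raters)) {
    set.seed(substream_seed(cfg$seed, 100000L + r))
    moving <- rep(FALSE, length(time))
    if (nrow(truth)) {
      for (i in seq_len(nrow(truth))) {
        if (stats::runif(1) < cfg$rater_miss_prob) next
        on <- truth$onset[i] + cfg$rater_onset_shift_ms / 1000 +
          stats::rnorm(1, 0, cfg$rater_jitter_sd_ms / 1000)
        off <- truth$offset[i] + cfg$rater_offset_shift_ms / 1000 +
          stats::rnorm(1, 0, cfg$rater_jitter_sd_ms / 1000)
        if (off < on + 2 * dt) off <- on + 2 * dt
        moving <- moving | (time >= on - 1e-12 & time < off - 1e-12)
      }
    }
    out[[r]] <- label_series(time, moving)
  }
  out
}

#' Simulate a multi-subject study
#'
#' Generates independent recordings for `n_subjects` subjects (per-subject
#' seeds derived from the config seed), in the shape the fitting routines
#' expect.
#'
#' @param n_subjects number of subjects.
#' @param cfg a [sim_config()] shared by all subjects (seeds differ).
#' @param savgol_window_ms smoothing window passed to [head_kinematics()].
#' @return list of subjects: each a list with `kin` ([head_kinematics()]),
#'   `raters` (list of [label_series()]), and `sim` (the full `hm_sim`).
#' @export
simulate_study <- function(n_subjects, cfg = sim_config(),
                           savgol_window_ms = 122) {
  lapply(seq_len(n_subjects), function(s) {
    scfg <- cfg
    scfg$seed <- substream_seed(cfg$seed, 7000000L + s)
    sim <- simulate_trace(scfg)
    list(kin = head_kinematics(sim$trace, savgol_window_ms = savgol_window_ms),
         raters = sim$rater_labels, sim = sim)
  })
}

#' Simulate annotated events with a prescribed main-sequence correlation
#'
#' Draws amplitudes uniformly and sets peak velocity = slope * amplitude +
#' Gaussian noise whose SD is calibrated in closed form so the population
#' Pearson correlation equals `r`:
#' sigma_eps = slope * sigma_A * sqrt(1 / r^2 - 1).
#'
#' @param n number of events.
#' @param r target population correlation in (0, 1].
#' @param slope main-sequence slope ((deg/s)/deg).
#' @param amplitude_range uniform amplitude range (deg).
#' @param seed integer seed.
#' @return a [head_events()] with `amplitude` and `peak_velocity` filled.
#' @export
simulate_main_sequence <- function(n, r, slope = 5,
                                   amplitude_range = c(3, 30), seed = 1L) {
  stopifnot(n >= 3, r > 0, r <= 1)
  set.seed(as.integer(seed))
  A <- stats::runif(n, amplitude_range[1], amplitude_range[2])
  sigma_a <- diff(amplitude_range) / sqrt(12)
  sigma_eps <- slope * sigma_a * sqrt(1 / r^2 - 1)
  v <- slope * A + stats::rnorm(n, 0, sigma_eps)
  onset <- seq_len(n)
  head_events(onset = onset, offset = onset + 0.5,
              amplitude = A, peak_velocity = v)
}
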