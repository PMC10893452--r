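# light smoothing (33 ms window, order 2) keeps boundary tests free of
# filter smear; noise-robust defaults are exercised on simulator traces
svt_sharp <- function(thr) svt_config(speed_threshold = thr,
                                      savgol_window_ms = 33,
                                      savgol_polyorder = 2L)

test_that("a raised-cosine bump above threshold yields one event at its support", {
  b <- bump_trace(vp = 30, dur = 0.5)
  kin <- head_kinematics(b$trace, savgol_window_ms = 33, savgol_polyorder = 2L)
  ev <- classify_svt(kin, svt_sharp(18.41))
  expect_equal(nrow(ev), 1L)
  # analytic acceleration zero crossings sit at the support edges
  dt <- 1 / 90
  expect_lt(abs(ev$onset - b$onset), dt + 1e-9)
  expect_lt(abs(ev$offset - b$offset), 1.5 * dt + 1e-9)
})

test_that("no events without super-threshold speed", {
  still <- head_trace(seq(0, 2, by = 1 / 90), euler = matrix(0, 181, 3))
  kin <- head_kinematics(still)
  expect_equal(nrow(classify_svt(kin, svt_config(speed_threshold = 5))), 0L)
})

test_that("two bumps separated by a sub-threshold valley give two disjoint events", {
  hz <- 90; t <- seq(0, 3, by = 1 / hz)
  sp <- function(c0) ifelse(abs(t - c0) < 0.25,
                            15 * (1 + cos(pi * (t - c0) / 0.25)), 0)
  speed <- sp(1) + sp(2)
  theta <- cumsum(speed) / hz
  tr <- head_trace(t, euler = cbind(0, theta, 0))
  kin <- head_kinematics(tr, savgol_window_ms = 33, savgol_polyorder = 2L)
  ev <- classify_svt(kin, svt_sharp(18.41))
  expect_equal(nrow(ev), 2L)
  expect_lt(ev$offset[1], ev$onset[2])
  expect_lt(abs(ev$onset[1] - 0.75), 0.03)
  expect_lt(abs(ev$onset[2] - 1.75), 0.03)
})

test_that("every event seeds from a super-threshold peak with onset < peak < offset", {
  sim <- simulate_trace(sim_config(n_trials = 6, seed = 17,
                                   wobble_per_trial = 1))
  kin <- head_kinematics(sim$trace)
  cfg <- svt_config(speed_threshold = 12)
  ev <- classify_svt(kin, cfg)
  expect_gt(nrow(ev), 0L)
  sm <- savgol_smooth(kin$speed, 11, 3)
  expect_true(all(diff(ev$onset) > 0))
  expect_true(all(ev$offset > ev$onset))
  if (nrow(ev) > 1) expect_true(all(ev$onset[-1] >= ev$offset[-nrow(ev)]))
  for (i in seq_len(nrow(ev))) {
    idx <- kin$time >= ev$onset[i] & kin$time < ev$offset[i]
    expect_gte(max(sm[idx]), cfg$speed_threshold)
    peak_t <- kin$time[idx][which.max(sm[idx])]
    expect_gt(peak_t, ev$onset[i])
    expect_lt(peak_t, ev$offset[i])
  }
})

test_that("pursuit plateaus are spanned as single events, not slivers", {
  sim <- simulate_trace(sim_config(n_trials = 4, seed = 23,
                                   condition = "pursuit"))
  kin <- head_kinematics(sim$trace)
  ev <- classify_svt(kin, svt_config(speed_threshold = 10))
  truth <- sim$truth_events
  pairs <- match_events(truth, ev)
  expect_equal(nrow(pairs), nrow(truth))
  # matched events cover most of each plateau
  cover <- (pairs$pred_offset - pairs$pred_onset) /
    (pairs$truth_offset - pairs$truth_onset)
  expect_true(all(cover > 0.8))
})
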