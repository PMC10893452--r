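test_that("a noise-free single trial realizes the configured amplitude exactly", {
  cfg <- sim_config(n_trials = 1, eccentricities = 50, noise_sd_deg = 0,
                    peak_vel_noise_sd = 0, seed = 2)
  sim <- simulate_trace(cfg)
  # head gain 0.6 of 50 deg eccentricity -> 30 deg movement
  expect_equal(sim$truth_events$amplitude[1], 30)
  ha <- head_angle_magnitude(sim$trace)
  expect_equal(max(ha), 30, tolerance = 1e-6)
  # trace-measured amplitude agrees with the declared truth amplitude
  kin <- head_kinematics(sim$trace)
  ann <- annotate_events(sim$truth_events, kin)
  expect_equal(ann$amplitude[1], 30, tolerance = 0.05)
})

test_that("identical seeds give bit-identical output; different seeds differ", {
  cfg <- sim_config(n_trials = 3, seed = 15)
  s1 <- simulate_trace(cfg)
  s2 <- simulate_trace(cfg)
  expect_identical(s1$trace$quat, s2$trace$quat)
  expect_identical(s1$truth_events, s2$truth_events)
  expect_identical(lapply(s1$rater_labels, `[[`, "moving"),
                   lapply(s2$rater_labels, `[[`, "moving"))
  s3 <- simulate_trace(sim_config(n_trials = 3, seed = 16))
  expect_false(identical(s1$trace$quat, s3$trace$quat))
})

test_that("generated ballistic events obey the main-sequence construction", {
  cfg <- sim_config(n_trials = 100, seed = 27)
  sim <- simulate_trace(cfg)
  ms <- main_sequence(sim$truth_events)
  expect_gte(ms$n, 200)
  expect_gte(ms$r, 0.9)
})

test_that("rater fidelity degrades with jitter and vanishes at full miss rate", {
  base <- sim_config(n_trials = 8, seed = 33, rater_jitter_sd_ms = 0,
                     rater_miss_prob = 0)
  sim <- simulate_trace(base)
  truth <- events_to_labels(sim$truth_events, sim$trace$time)
  for (r in sim$rater_labels) {
    expect_equal(cohens_kappa(label_series(r$time, r$moving), truth)$kappa, 1)
  }

  inter_kappa <- function(jit) {
    cfg <- sim_config(n_trials = 8, seed = 33, rater_jitter_sd_ms = jit,
                      rater_miss_prob = 0)
    s <- simulate_trace(cfg)
    cohens_kappa(s$rater_labels[[1]], s$rater_labels[[2]])$kappa
  }
  ks <- vapply(c(0, 20, 60, 120), inter_kappa, numeric(1))
  expect_equal(ks[1], 1)
  expect_true(all(diff(ks) < 0))

  gone <- simulate_trace(sim_config(n_trials = 4, seed = 33,
                                    rater_miss_prob = 1))
  expect_false(any(gone$rater_labels[[1]]$moving))
})

test_that("trials carry markers, masked raters and in-trial truth events", {
  sim <- simulate_trace(sim_config(n_trials = 5, seed = 37,
                                   corrective_prob = 0.5))
  mk <- sim$trace$markers
  expect_equal(sum(mk$kind == "trial_start"), 5L)
  expect_equal(sum(mk$kind == "target_on"), 5L)
  expect_equal(sum(mk$kind == "response"), 5L)
  expect_true(sim$trace$uniform)
  # truth events are disjoint and inside the recording
  tr_ev <- sim$truth_events
  expect_true(all(tr_ev$onset >= min(sim$trace$time)))
  expect_true(all(tr_ev$offset <= max(sim$trace$time) + 1 / 90))
  if (nrow(tr_ev) > 1) {
    expect_true(all(tr_ev$onset[-1] >= tr_ev$offset[-nrow(tr_ev)] - 1e-9))
  }
  # rater masks restrict scoring to trial windows
  expect_false(is.null(sim$rater_labels[[1]]$mask))
})

test_that("simulate_study yields independent subjects in fitting shape", {
  study <- simulate_study(3, sim_config(n_trials = 2, seed = 41))
  expect_length(study, 3L)
  for (s in study) {
    expect_s3_class(s$kin, "head_kinematics")
    expect_length(s$raters, 2L)
  }
  expect_false(identical(study[[1]]$kin$speed, study[[2]]$kin$speed))
})
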