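# single smooth movement along a compass direction: whole-trace velocity
# bump so the filtered acceleration has exactly one interior zero crossing
directed_move_trace <- function(dir_deg, amp = 20, dur = 2, hz = 90) {
  t <- seq(0, dur, by = 1 / hz)
  prog <- (1 - cos(pi * t / dur)) / 2
  theta <- amp * prog
  dir_rad <- dir_deg * pi / 180
  axis <- c(-sin(dir_rad), cos(dir_rad), 0)
  half <- theta * pi / 360
  head_trace(t, quat = cbind(cos(half), sin(half) %o% axis))
}

test_that("single-axis ramps produce one cardinal event; two-axis ramps a diagonal", {
  kinE <- head_kinematics(directed_move_trace(0))
  evE <- classify_dizco(kinE, dizco_config(accel_magnitude_threshold = 1))
  expect_equal(nrow(evE), 1L)
  expect_equal(evE$direction, "E")

  kinN <- head_kinematics(directed_move_trace(90))
  evN <- classify_dizco(kinN, dizco_config(accel_magnitude_threshold = 1))
  expect_equal(evN$direction, "N")

  kinNE <- head_kinematics(directed_move_trace(45))
  evNE <- classify_dizco(kinNE, dizco_config(accel_magnitude_threshold = 1))
  expect_equal(evNE$direction, "NE")
})

test_that("stationary noise below the magnitude threshold yields zero events", {
  set.seed(12)
  t <- seq(0, 3, by = 1 / 90)
  tr <- head_trace(t, euler = matrix(rnorm(3 * length(t), 0, 0.01),
                                     ncol = 3))
  kin <- head_kinematics(tr)
  ev <- classify_dizco(kin, dizco_config(accel_magnitude_threshold = 1e5))
  expect_equal(nrow(ev), 0L)
})

test_that("mirroring the horizontal axis flips east/west labels only", {
  flip_lr <- c(E = "W", W = "E", NE = "NW", NW = "NE", SE = "SW", SW = "SE",
               N = "N", S = "S")
  for (dir in c(0, 45, 90, 225)) {
    tr <- directed_move_trace(dir)
    ev <- classify_dizco(head_kinematics(tr),
                         dizco_config(accel_magnitude_threshold = 1))
    # mirror: negate yaw, keep pitch (reflect the movement left-right)
    eul <- quat_to_euler(tr$quat)
    eul[, "yaw"] <- -eul[, "yaw"]
    evm <- classify_dizco(head_kinematics(head_trace(tr$time, euler = eul)),
                          dizco_config(accel_magnitude_threshold = 1))
    expect_equal(evm$direction, unname(flip_lr[ev$direction]))
  }
})

test_that("the rest-percentile default threshold classifies simulated trials sensibly", {
  sim <- simulate_trace(sim_config(n_trials = 6, seed = 29))
  kin <- head_kinematics(sim$trace)
  ev <- classify_dizco(kin)
  expect_gt(nrow(ev), 0L)
  # events cover the orienting movements: each truth event overlaps >= 1
  truth <- sim$truth_events
  overlaps <- vapply(seq_len(nrow(truth)), function(i) {
    any(ev$onset < truth$offset[i] & ev$offset > truth$onset[i])
  }, logical(1))
  expect_gt(mean(overlaps), 0.9)
})
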