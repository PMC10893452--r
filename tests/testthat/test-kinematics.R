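test_that("angular speed handles constant-rate, stationary and composed rotations", {
  expect_equal(angular_speed(constant_yaw_trace(20, 2)),
               rep(20, 181), tolerance = 1e-6)
  still <- head_trace(seq(0, 1, by = 1 / 90), euler = matrix(0, 91, 3))
  expect_equal(angular_speed(still), rep(0, 91))

  # simultaneous 3 deg/s yaw + 4 deg/s pitch about orthogonal axes -> 5 deg/s;
  # expected value from composing the rotations numerically step by step
  hz <- 90; t <- seq(0, 1, by = 1 / hz)
  qy <- quat_from_axis_angle(c(0, 1, 0), 3 / hz)
  qx <- quat_from_axis_angle(c(1, 0, 0), 4 / hz)
  step <- headmov:::quat_multiply(qy, qx)
  q <- matrix(0, length(t), 4); q[1, ] <- c(1, 0, 0, 0)
  for (i in 2:length(t)) q[i, ] <- headmov:::quat_multiply(step, q[i - 1, ])
  expected <- quat_angle(q[1, ], q[2, ]) * hz   # oracle: measured geodesic step
  sp <- angular_speed(head_trace(t, quat = q))
  expect_equal(sp, rep(expected, length(t)), tolerance = 1e-9)
  expect_equal(expected, 5, tolerance = 1e-3)

  expect_error(angular_speed(head_trace(0, euler = matrix(0, 1, 3))),
               "at least 2")
})

test_that("angular speed is time-symmetric", {
  set.seed(3)
  sim <- simulate_trace(sim_config(n_trials = 2, seed = 3))
  tr <- sim$trace
  fwd <- angular_speed(tr)
  rev_tr <- head_trace(tr$time, quat = tr$quat[rev(seq_along(tr$time)), ])
  bwd <- angular_speed(rev_tr)
  # interior samples mirror exactly; the copied-endpoint convention touches
  # only the first sample of each direction
  expect_equal(fwd[-1], rev(bwd)[-length(bwd)], tolerance = 1e-9)
})

test_that("per-axis velocity recovers pure yaw, survives the 180-degree wrap, and squares to total speed", {
  v <- per_axis_angular_velocity(constant_yaw_trace(20, 2))
  expect_equal(unname(v$vel[, "y"]), rep(20, 181), tolerance = 1e-6)
  expect_lt(max(abs(v$vel[, c("x", "z")])), 1e-6)

  # crossing the 180-degree wrap at constant rate must not spike
  t <- seq(0, 10, by = 1 / 90)
  wrap <- head_trace(t, euler = cbind(0, 40 * t, 0))  # passes 180 and 360
  vw <- per_axis_angular_velocity(wrap)
  expect_lt(max(abs(vw$vel[, "y"] - 40)), 1e-6)

  # random smooth trace: axis rates' sum of squares ~ total speed^2, with
  # the geodesic speed computed on the same central two-sample stencil as
  # the axis rates
  sim <- simulate_trace(sim_config(n_trials = 2, seed = 11))
  kin <- head_kinematics(sim$trace)
  n <- length(kin$time)
  q <- sim$trace$quat
  sp_c <- quat_angle(q[1:(n - 2), ], q[3:n, ]) * kin$rate / 2
  mid <- 2:(n - 1)
  ok <- !kin$gimbal[mid] & sp_c > 5
  rel <- abs(sqrt(rowSums(kin$vel[mid, ][ok, ]^2)) - sp_c[ok]) / sp_c[ok]
  expect_lt(stats::median(rel), 0.05)
})

test_that("head-angle magnitude matches single-axis rotations and ignores roll", {
  one <- function(eul) head_angle_magnitude(
    head_trace(0, euler = matrix(eul, 1)))
  expect_equal(one(c(0, 0, 0)), 0, tolerance = 1e-9)
  expect_equal(one(c(0, 30, 0)), 30, tolerance = 1e-9)
  expect_equal(one(c(90, 0, 0)), 90, tolerance = 1e-9)
  expect_equal(one(c(0, 30, 75)), one(c(0, 30, 0)), tolerance = 1e-9)
  set.seed(5)
  for (roll in runif(5, -180, 180)) {
    expect_equal(one(c(20, 40, roll)), one(c(20, 40, 0)), tolerance = 1e-9)
  }
})

test_that("angular acceleration: constant, ramp and raised-cosine bump", {
  expect_equal(angular_acceleration(rep(7, 50), 1 / 90), rep(0, 50))
  t <- seq(0, 1, by = 1 / 90)
  expect_equal(angular_acceleration(90 * t, 1 / 90), rep(90, length(t)),
               tolerance = 1e-9)
  # raised-cosine speed bump: acceleration crosses zero at the peak sample
  sp <- 15 * (1 - cos(2 * pi * t))
  a <- angular_acceleration(sp, 1 / 90)
  peak <- which.max(sp)
  zc <- which(a[-1] * a[-length(a)] <= 0)
  expect_lte(min(abs(zc - peak)), 1)
})

test_that("Savitzky-Golay reproduces low-order polynomials and shrinks noise", {
  x <- seq(0, 1, length.out = 101)
  poly <- 2 - 3 * x + 0.5 * x^2 + 4 * x^3
  expect_equal(savgol_smooth(poly, 11, 3), poly, tolerance = 1e-9)
  expect_equal(savgol_smooth(rep(3.7, 51), 11, 3), rep(3.7, 51),
               tolerance = 1e-12)
  set.seed(8)
  noise <- rnorm(500)
  expect_lt(stats::var(savgol_smooth(noise, 11, 3)), stats::var(noise))
  expect_error(savgol_smooth(1:5, 11, 3), "longer")
  expect_error(savgol_smooth(1:50, 10, 3), "odd")
})

test_that("zero-phase low-pass has the designed pass/stop behaviour", {
  hz <- 90; t <- (0:899) / hz
  pass <- lowpass_zero_phase(sin(2 * pi * 2 * t), 10, hz)
  expect_gt(max(abs(pass[300:600])), 0.98)
  stop_ <- lowpass_zero_phase(sin(2 * pi * 30 * t), 10, hz)
  expect_lt(max(abs(stop_[300:600])), 0.1)
  dc <- lowpass_zero_phase(rep(2.5, 300), 10, hz)
  expect_equal(dc[50:250], rep(2.5, 201), tolerance = 1e-6)
  expect_error(lowpass_zero_phase(1:10, 50, 90), "Nyquist")
})
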