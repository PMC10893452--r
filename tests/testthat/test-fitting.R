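study4 <- NULL
get_study <- function() {
  if (is.null(study4)) {
    study4 <<- simulate_study(4, sim_config(n_trials = 6, seed = 83,
                                            wobble_per_trial = 1))
  }
  study4
}

test_that("a single-threshold grid reproduces direct evaluation", {
  study <- get_study()
  gs <- grid_search(study, "svt", grid = 12)
  sub <- study[[1]]
  mask <- trial_mask(sub$kin$time, sub$kin$markers)
  labs <- classify_labels(sub$kin, "svt", 12)
  direct <- mean(vapply(sub$raters, function(r)
    cohens_kappa(labs, r, mask = mask)$kappa, numeric(1)))
  expect_equal(gs$kappa[1, 1], direct, tolerance = 1e-12)
  expect_equal(unname(gs$mean_kappa), mean(gs$kappa[, 1]))
})

test_that("the kappa map peaks near the generative boundary and is single-peaked", {
  study <- get_study()
  grid <- seq(4, 30, by = 1)
  gs <- grid_search(study, "svt", grid)
  best <- grid[which.max(gs$mean_kappa)]
  expect_lt(abs(best - 10), 2.01)   # wobble ceiling at 10 deg/s
  # rises to the peak, then never rises again after dropping (coarse unimodality)
  mk <- as.numeric(gs$mean_kappa)
  pk <- which.max(mk)
  expect_true(all(diff(mk[1:pk]) >= -1e-9))
  after <- mk[pk:length(mk)]
  expect_true(all(after <= mk[pk] + 1e-9))
})

test_that("leave-one-out is deterministic, exchangeable and structurally sound", {
  study <- get_study()
  grid <- seq(6, 20, by = 1)
  fit1 <- fit_loo(study, "svt", grid)
  fit2 <- fit_loo(study, "svt", grid)
  expect_identical(fit1$per_fold, fit2$per_fold)
  expect_equal(nrow(fit1$per_fold), length(study))
  expect_true(all(fit1$per_fold$threshold %in% grid))
  expect_equal(fit1$kappa_se,
               sd(fit1$per_fold$kappa) / sqrt(length(study)))

  # reordering subjects permutes folds but not the aggregates
  fitr <- fit_loo(rev(study), "svt", grid)
  expect_equal(fitr$mean_kappa, fit1$mean_kappa, tolerance = 1e-12)
  expect_equal(fitr$mean_threshold, fit1$mean_threshold, tolerance = 1e-12)

  expect_error(fit_loo(study[1:2], "svt", grid), "at least 3")
})

test_that("statistically identical subjects select identical thresholds", {
  one <- simulate_study(1, sim_config(n_trials = 5, seed = 89,
                                      wobble_per_trial = 1))[[1]]
  clones <- list(one, one, one, one)
  fit <- fit_loo(clones, "svt", seq(6, 20, by = 1))
  expect_equal(fit$threshold_se, 0)
  expect_equal(length(unique(fit$per_fold$threshold)), 1L)
})

test_that("held-out kappa does not beat the in-sample optimum on average", {
  study <- get_study()
  grid <- seq(6, 20, by = 2)
  gs <- grid_search(study, "svt", grid)
  fit <- fit_loo(study, "svt", grid)
  expect_lte(fit$mean_kappa, max(gs$mean_kappa) + 1e-9)
})

test_that("fit_report assembles one row per condition and algorithm", {
  study <- get_study()
  fit <- fit_loo(study, "svt", seq(8, 14, by = 2))
  rep_ <- fit_report(list(instant = list(svt = fit)))
  expect_equal(nrow(rep_), 1L)
  expect_equal(rep_$condition, "instant")
  expect_equal(rep_$kappa, fit$mean_kappa)
})
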