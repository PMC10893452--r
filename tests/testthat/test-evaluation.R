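test_that("kappa matches the contingency oracle, is symmetric, and handles edge cases", {
  t4 <- 0:3
  # identical non-constant labelings
  a <- label_series(t4, c(1, 1, 0, 0))
  expect_equal(cohens_kappa(a, a)$kappa, 1)
  # worked 2x2 example
  b <- label_series(t4, c(1, 0, 0, 0))
  k <- cohens_kappa(a, b)
  expect_equal(k$po, 0.75)
  expect_equal(k$pe, 0.5)
  expect_equal(k$kappa, 0.5)
  expect_equal(cohens_kappa(b, a)$kappa, k$kappa)   # symmetry
  # undefined when both labelers are constant and identical
  cc <- label_series(t4, rep(1, 4))
  expect_true(is.na(cohens_kappa(cc, cc)$kappa))
  expect_error(cohens_kappa(a, label_series(0:4, rep(0, 5))), "length")

  set.seed(61)
  for (rep in 1:100) {
    n <- sample(10:200, 1)
    x <- runif(n) < runif(1, 0.2, 0.8)
    y <- runif(n) < runif(1, 0.2, 0.8)
    ours <- cohens_kappa(label_series(seq_len(n), x),
                         label_series(seq_len(n), y))$kappa
    expect_equal(ours, oracle_kappa(x, y), tolerance = 1e-12)
    expect_equal(ours, e1071::classAgreement(table(x, y))$kappa,
                 tolerance = 1e-12)
  }
})

test_that("masked kappa equals kappa on the extracted sub-series", {
  set.seed(67)
  n <- 500
  x <- runif(n) < 0.4; y <- runif(n) < 0.4
  mask <- runif(n) < 0.6
  t <- seq_len(n)
  k_masked <- cohens_kappa(label_series(t, x, mask), label_series(t, y))$kappa
  k_sub <- cohens_kappa(label_series(t[mask], x[mask]),
                        label_series(t[mask], y[mask]))$kappa
  expect_equal(k_masked, k_sub)
})

test_that("rater union is the per-sample OR with boolean-algebra structure", {
  t <- 1:6
  a <- label_series(t, c(1, 1, 0, 0, 0, 0))
  b <- label_series(t, c(0, 0, 0, 1, 1, 0))
  u <- merge_raters(list(a, b))
  expect_equal(u$moving, c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE))
  sub <- label_series(t, c(1, 0, 0, 0, 0, 0))     # subset of a
  expect_equal(merge_raters(list(a, sub))$moving, a$moving)
  c3 <- label_series(t, c(0, 0, 1, 0, 0, 0))
  expect_equal(merge_raters(list(a, b, c3))$moving,
               merge_raters(list(c3, merge_raters(list(b, a))))$moving)
  expect_error(merge_raters(list(a, label_series(1:5, rep(0, 5)))), "length")
})

test_that("midpoint matching applies containment, duplicate removal and the half-open bound", {
  # containment: truth midpoint 150 ms inside pred [140, 260) ms
  truth <- head_events(onset = 0.100, offset = 0.200)
  pred <- head_events(onset = 0.140, offset = 0.260)
  expect_equal(nrow(match_events(truth, pred)), 1L)

  # two truth midpoints inside one pred event: no one-to-one pairing
  truth2 <- head_events(onset = c(0.1, 0.3), offset = c(0.2, 0.4))
  pred2 <- head_events(onset = 0.05, offset = 0.5)
  expect_equal(nrow(match_events(truth2, pred2)), 0L)

  # pred ending exactly at the truth midpoint: excluded by the bound
  pred3 <- head_events(onset = 0.05, offset = 0.150)
  expect_equal(nrow(match_events(truth, pred3)), 0L)
})

test_that("matching is one-to-one on random disjoint event sets", {
  set.seed(71)
  for (rep in 1:30) {
    mk_ev <- function() {
      k <- sample(3:12, 1)
      on <- sort(runif(k, 0, 10))
      off <- on + runif(k, 0.05, 0.5)
      off <- pmin(off, c(on[-1], Inf) - 1e-4)
      head_events(onset = on, offset = off)
    }
    pairs <- match_events(mk_ev(), mk_ev())
    expect_equal(anyDuplicated(pairs$truth_idx), 0L)
    expect_equal(anyDuplicated(pairs$pred_idx), 0L)
  }
})

test_that("bias metrics follow the human-minus-algorithm sign convention", {
  truth <- head_events(onset = 0.110, offset = 0.210, amplitude = 12)
  pred <- head_events(onset = 0.100, offset = 0.205, amplitude = 10)
  b <- bias_metrics(match_events(truth, pred))
  expect_equal(b$onset_bias, 10, tolerance = 1e-9)
  expect_equal(b$offset_bias, 5, tolerance = 1e-9)
  expect_equal(b$duration_bias, -5, tolerance = 1e-9)
  expect_equal(b$amplitude_bias, 2, tolerance = 1e-9)

  # identical events: all biases zero
  b0 <- bias_metrics(match_events(truth, truth))
  expect_equal(b0$onset_bias, 0)
  expect_equal(b0$duration_bias, 0)

  # constructed shift: pred onset +10 ms, offset -5 ms
  on <- seq(0, 9) + 0.2; off <- on + 0.3
  truth3 <- head_events(onset = on, offset = off)
  pred3 <- head_events(onset = on + 0.010, offset = off - 0.005)
  b3 <- bias_metrics(match_events(truth3, pred3))
  expect_equal(b3$onset_bias, -10, tolerance = 1e-9)
  expect_equal(b3$offset_bias, 5, tolerance = 1e-9)
  expect_equal(b3$duration_bias, 15, tolerance = 1e-9)
  # duration bias is offset bias minus onset bias by construction
  expect_equal(b3$duration_bias, b3$offset_bias - b3$onset_bias,
               tolerance = 1e-12)

  expect_equal(bias_metrics(match_events(head_events(), head_events()))$n_pairs, 0L)
})

test_that("main sequence: perfect linearity, null, and degenerate inputs", {
  ev <- head_events(onset = 1:10, offset = 1:10 + 0.3,
                    amplitude = seq(2, 20, 2),
                    peak_velocity = 2 * seq(2, 20, 2))
  expect_equal(main_sequence(ev)$r, 1, tolerance = 1e-12)

  set.seed(73)
  evn <- head_events(onset = 1:1000, offset = 1:1000 + 0.3,
                     amplitude = runif(1000, 2, 30),
                     peak_velocity = runif(1000, 10, 150))
  expect_lt(abs(main_sequence(evn)$r), 0.07)

  degen <- head_events(onset = 1:5, offset = 1:5 + 0.1,
                       amplitude = rep(10, 5),
                       peak_velocity = runif(5, 10, 50))
  res <- main_sequence(degen)
  expect_true(res$degenerate)
  expect_true(is.na(res$r))
  expect_error(main_sequence(head_events(onset = 1, offset = 2,
                                         amplitude = 1,
                                         peak_velocity = 2)), "at least 3")
})
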