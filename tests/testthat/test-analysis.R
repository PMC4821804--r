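test_that("calibration curve summarises sorted-confidence windows", {
  all_right <- tibble::tibble(confidence = runif(100), correct = TRUE)
  cc <- confidence_performance_curve(all_right)
  expect_true(all(cc$prop_correct == 1))
  expect_equal(nrow(cc), 100 - ceiling(0.05 * 100) + 1)

  # correctness independent of confidence: flat curve at the base rate
  withr::with_seed(12, {
    ind <- tibble::tibble(confidence = runif(4000),
                          correct = runif(4000) < 0.7)
  })
  ci <- confidence_performance_curve(ind)
  # window means stay within binomial error of 0.7 (window n = 200)
  expect_true(all(abs(ci$prop_correct - 0.7) <
                    5 * sqrt(0.7 * 0.3 / 200)))

  expect_error(confidence_performance_curve(all_right[1:10, ],
                                            window_fraction = 0.05),
               "Too few")
})

test_that("perceptual learning index is a zero-mean baseline-free residual", {
  withr::with_seed(2, {
    pre <- runif(12, 6, 14)
    post <- pre - 1 + rnorm(12, 0, 0.8)
  })
  pli <- perceptual_learning_index(pre, post)
  expect_equal(mean(pli$learning_index), 0, tolerance = 1e-12)
  expect_equal(unname(cor(pli$learning_index, pre)), 0, tolerance = 1e-10)

  # worked 3-subject case: improvement exactly linear in pre
  exact <- perceptual_learning_index(c(10, 12, 14), c(9, 10, 11))
  expect_equal(exact$learning_index, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(exact$improvement, c(-1, -2, -3))

  expect_error(perceptual_learning_index(c(8, 8, 8), c(7, 6, 5)),
               "Zero variance")
  expect_error(perceptual_learning_index(c(8, 9), c(7, 8)), "3 subjects")
})

test_that("run-slope summary fits run means by least squares", {
  d <- tibble::tibble(run = rep(1:6, each = 10), y = rep(2 * (1:6), each = 10))
  expect_equal(slope_per_run(d, "y")$slope, 2)
  expect_equal(slope_per_run(dplyr::mutate(d, y = 5), "y")$slope, 0)
  expect_equal(nrow(slope_per_run(d, "y")$run_means), 6)
  expect_error(slope_per_run(d[d$run == 1, ], "y"), "two runs")
})

test_that("Fisher-z group test matches first-principles computation", {
  expect_equal(fisher_z_group_test(c(0.5, 0.5, 0.5))$mean_z, atanh(0.5))
  expect_equal(atanh(0.5), 0.549306, tolerance = 1e-6)
  expect_equal(fisher_z_group_test(rep(0, 5))$t, 0)
  expect_error(fisher_z_group_test(c(0.5, 1)), "< 1")

  withr::with_seed(9, r <- runif(15, -0.4, 0.8))
  out <- fisher_z_group_test(r)
  z <- atanh(r)
  t_manual <- mean(z) / (sd(z) / sqrt(length(z)))
  expect_equal(out$t, t_manual)
  expect_equal(out$p_value,
               2 * stats::pt(abs(t_manual), length(z) - 1, lower.tail = FALSE))
})

test_that("simulated BOLD time courses have the anticipatory/outcome shape", {
  b0 <- simulate_bold("absent_pe")
  expect_equal(nrow(b0), 240)
  expect_equal(range(b0$time), c(-4, 20 - 0.1))
  expect_equal(diff(b0$time)[1], 0.1)

  # zero neural input -> zero output (linearity)
  bz <- simulate_bold("absent_pe", anticipation = 0)
  expect_true(all(bz$bold == 0))

  # anticipation response peaks 4-6 s after the trial onset at t = -2 s
  peak_t <- b0$time[which.max(b0$bold)]
  expect_gte(peak_t, -2 + 4)
  expect_lte(peak_t, -2 + 6)

  # outcome deflections mirror the prediction-error sign
  bp <- simulate_bold("positive_pe")
  bn <- simulate_bold("negative_pe")
  post <- b0$time > 0
  expect_equal(bp$bold - b0$bold, -(bn$bold - b0$bold), tolerance = 1e-12)
  dp <- (bp$bold - b0$bold)[post]
  dn <- (bn$bold - b0$bold)[post]
  # the difference curves carry the prediction-error sign at their extrema
  expect_gt(dp[which.max(abs(dp))], 0.9)
  expect_lt(dn[which.max(abs(dn))], -0.9)
})

test_that("parametric regressors are mean-centred HRF-convolved trains", {
  traj <- tibble::tibble(
    c_bar_pre = c(0.4, 0.6, 0.5), cpe = c(0.2, -0.1, 0.3),
    t_trial_onset = c(2, 30, 58), t_stimulus_onset = c(4, 32.5, 60.4))
  reg <- build_parametric_regressors(traj, TR = 2, duration = 100)
  expect_equal(reg$time, seq(0, 100, by = 2))

  # constant modulator vanishes after mean-centring
  flat <- build_parametric_regressors(
    dplyr::mutate(traj, c_bar_pre = 0.7), TR = 2, duration = 100)
  expect_true(all(flat$expected_confidence == 0))

  # two disjoint events: the regressor is the sum of shifted, weighted
  # copies of the sampled HRF (a single event mean-centres to zero)
  two <- tibble::tibble(c_bar_pre = c(1, 0), cpe = c(1, -1),
                        t_trial_onset = c(0, 20),
                        t_stimulus_onset = c(2, 22))
  r2 <- build_parametric_regressors(two, TR = 2, duration = 60, dt = 0.1)
  hrf <- hrf_double_gamma(seq(0, 32, by = 0.1))
  # expected: +-0.5-weighted impulses at 0 and 20 s, HRF-convolved
  grid <- seq(0, 60, by = 0.1)
  train <- numeric(length(grid)); train[1] <- 0.5; train[201] <- -0.5
  expected <- conflearn:::convolve_truncate(train, hrf)
  keep <- seq(1, length(grid), by = 20)
  expect_equal(r2$expected_confidence, expected[keep], tolerance = 1e-8)

  expect_error(build_parametric_regressors(traj, duration = 50), "within")
})
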