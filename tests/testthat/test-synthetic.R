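test_that("surrogate energy streams have the designated/opposite structure", {
  spec <- observer_spec()
  s1 <- generate_energy_stream(rep(8, 100), rep(c("cw", "ccw"), 50), spec,
                               seed = 6)
  expect_identical(s1, generate_energy_stream(rep(8, 100),
                                              rep(c("cw", "ccw"), 50),
                                              spec, seed = 6))
  expect_true(all(s1$E_ccw_raw >= 0 & s1$E_cw_raw >= 0))
  # designated orientation carries the contrast-driven energy
  des <- ifelse(s1$true_orientation == "cw", s1$E_cw_raw, s1$E_ccw_raw)
  opp <- ifelse(s1$true_orientation == "cw", s1$E_ccw_raw, s1$E_cw_raw)
  expect_gt(mean(des), mean(opp))

  # at zero contrast the two orientations are exchangeable
  s0 <- generate_energy_stream(rep(0, 4000), rep(c("cw", "ccw"), 2000),
                               spec, seed = 7)
  des0 <- ifelse(s0$true_orientation == "cw", s0$E_cw_raw, s0$E_ccw_raw)
  opp0 <- ifelse(s0$true_orientation == "cw", s0$E_ccw_raw, s0$E_cw_raw)
  expect_lt(abs(mean(des0) - mean(opp0)), 0.02)

  expect_error(observer_spec(energy_gain = -1), "energy_gain")
})

test_that("gain calibration puts the observer at the staircase target", {
  g <- calibrate_energy_gain(observer_spec(), target = 0.8035, contrast = 8,
                             n_trials = 2000, seed = 4)
  acc <- mean(simulate_fixed_contrast(
    observer_spec(energy_gain = g), 8, 5000, seed = 99,
    learning = FALSE)$correct)
  expect_gte(acc, 0.78)
  expect_lte(acc, 0.82)
})

test_that("simulated experiments reproduce the session structure", {
  ex <- simulate_experiment(observer_spec(), experiment_design(), seed = 17)
  tr <- dplyr::filter(ex$trials, session == "training")
  expect_equal(sort(unique(tr$run)), 1:9)
  expect_true(all(table(tr$run) == 48))
  # constant-contrast control interleaved on exactly half the trials
  by_run <- tapply(tr$condition == "constant", tr$run, sum)
  expect_true(all(by_run == 24))
  const <- dplyr::filter(tr, condition == "constant")
  expect_equal(length(unique(const$contrast)), 1L)
  # only the trained axis appears in training; both axes in the tests
  expect_equal(unique(tr$axis), "vertical")
  expect_setequal(unique(ex$trials$axis[ex$trials$session == "pre_test"]),
                  c("vertical", "horizontal"))
  expect_equal(nrow(ex$thresholds), 4)
  # event times increase within a run, stimulus after trial onset
  r1 <- dplyr::filter(tr, run == 1)
  expect_true(all(diff(r1$t_trial_onset) > 0))
  expect_true(all(r1$t_stimulus_onset > r1$t_trial_onset))

  # bit-exact reproducibility from (spec, design, seed)
  ex2 <- simulate_experiment(observer_spec(), experiment_design(), seed = 17)
  expect_identical(ex$trials, ex2$trials)
})

test_that("generated confidence tracks accuracy and learning reduces thresholds", {
  # monotone confidence-accuracy link for the calibrated observer
  sim <- simulate_fixed_contrast(observer_spec(), 8, 3000, seed = 23)
  curve <- confidence_performance_curve(sim)
  expect_gt(cor(curve$confidence, curve$prop_correct,
                method = "spearman"), 0.5)

  # a clearly learning observer: across 20 simulated experiments the
  # trained-axis threshold drops on average from pre- to post-test, and
  # the in-training staircase contrast declines across runs
  fast <- observer_spec(true_params = model_params(alpha_w = 0.02))
  res <- vapply(1:20, function(s) {
    e <- simulate_experiment(fast, seed = s)
    th <- e$thresholds
    stair <- dplyr::filter(e$trials, session == "training",
                           condition == "staircase")
    c(th$threshold[th$session == "post_test" & th$axis == "vertical"] -
        th$threshold[th$session == "pre_test" & th$axis == "vertical"],
      slope_per_run(stair, "contrast")$slope)
  }, c(0, 0))
  expect_lt(mean(res[1, ]), 0)   # mean threshold improvement
  expect_lt(mean(res[2, ]), 0)   # mean in-training contrast slope
  expect_gt(mean(res[2, ] < 0), 0.5)
})

test_that("image-derived energies agree in rank order with the surrogate", {
  # slow path: actual synthesised stimuli put more energy on the
  # designated than the opposite orientation, as the surrogate assumes
  bank <- build_filter_bank(orientations = c(-20, 20))
  des <- opp <- numeric(4)
  for (i in 1:4) {
    th <- c(20, -20)[(i %% 2) + 1]
    spec <- stimulus_spec(peak_contrast_cp = 50, orientation_theta = th)
    img <- make_stimulus(spec, seed = 40 + i)
    des[i] <- orientation_energy(img, bank, th)
    opp[i] <- orientation_energy(img, bank, -th)
  }
  expect_true(all(des > opp))
})
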