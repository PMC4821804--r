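test_that("decision stage reproduces hand-computed values", {
  st <- list(w_ccw_ccw = 1, w_cw_cw = 1, w_ccw_cw = 0.1, w_cw_ccw = 0.1)
  A <- decision_activities(0.8, 0.2, st)
  expect_equal(unname(A), c(0.82, 0.28))
  expect_equal(decision_value(A[["A_ccw"]], A[["A_cw"]]), -0.54)
  expect_equal(decision_value(1, 2), -decision_value(2, 1))

  # swapping energies under symmetric weights swaps the activities
  A2 <- decision_activities(0.2, 0.8, st)
  expect_equal(unname(A2), rev(unname(A)))

  expect_equal(choice_probability(0, 7), 0.5)
  expect_equal(choice_probability(3, 0), 0.5)
  expect_equal(choice_probability(1, 2), 0.880797, tolerance = 1e-6)
  expect_gt(choice_probability(1e6, 10), 0)  # overflow-guarded

  expect_equal(decisional_certainty(0, 3), 0)
  expect_equal(decisional_certainty(-0.2, 3), 0.6)
  expect_equal(decisional_certainty(0.37, 2), decisional_certainty(-0.37, 2))
})

test_that("confidence prediction error and its running average update", {
  expect_equal(confidence_prediction_error(0.9, 0.5), 0.4)
  expect_equal(confidence_prediction_error(0.3, 0.3), 0)
  expect_error(confidence_prediction_error(1.2, 0.5), "\\[0, 1\\]")

  expect_equal(update_expected_confidence(0.5, 0.4, 0.5), 0.7)
  expect_equal(update_expected_confidence(0.5, 0.4, 0), 0.5)

  # feeding a constant confidence shrinks the gap geometrically
  c_bar <- 0.1; alpha <- 0.3; target <- 0.8
  for (t in 1:25) {
    c_bar <- update_expected_confidence(
      c_bar, confidence_prediction_error(target, c_bar), alpha)
  }
  expect_equal(abs(c_bar - target), abs(0.1 - target) * (1 - alpha)^25,
               tolerance = 1e-12)

  # c_bar stays inside [0, 1] for arbitrary confidence sequences
  withr::with_seed(3, {
    for (rep in 1:20) {
      cb <- runif(1); a <- runif(1)
      for (cc in runif(50)) {
        cb <- update_expected_confidence(
          cb, confidence_prediction_error(cc, cb), a)
      }
      expect_true(cb >= 0 && cb <= 1)
    }
  })
})

test_that("weight update touches only the chosen unit's connections", {
  st <- model_state(model_params())
  up <- update_weights(st, delta = 0.4, E_ccw = 0.1, E_cw = 0.6,
                       A_choice = 0.5, choice = "cw", alpha_w = 0.01)
  expect_equal(up$w_cw_cw - st$w_cw_cw, 0.01 * 0.4 * 0.6 * 0.5)  # 0.0012
  expect_equal(up$w_ccw_cw - st$w_ccw_cw, 0.01 * 0.4 * 0.1 * 0.5)
  expect_equal(up$w_ccw_ccw, st$w_ccw_ccw)
  expect_equal(up$w_cw_ccw, st$w_cw_ccw)

  same <- update_weights(st, delta = 0, E_ccw = 0.5, E_cw = 0.5,
                         A_choice = 0.5, choice = "ccw", alpha_w = 0.2)
  expect_equal(same, st)

  ccw <- update_weights(st, 0.4, 0.1, 0.6, 0.5, "ccw", 0.01)
  expect_equal(ccw$w_cw_cw, st$w_cw_cw)
  expect_equal(ccw$w_ccw_cw, st$w_ccw_cw)
})

test_that("censored-Gaussian confidence likelihood is correct and proper", {
  expect_equal(confidence_log_density(0.5, 0.5, 0.2),
               log(1 / (0.2 * sqrt(2 * pi))))
  expect_equal(confidence_log_density(0, 0, 0.2), log(0.5))
  expect_equal(confidence_log_density(1, 1, 0.3), log(0.5))
  expect_error(confidence_log_density(0.5, 0.5, 0), "sigma_c")
  expect_error(confidence_log_density(1.5, 0.5, 0.2), "\\[0, 1\\]")

  # boundary masses plus interior density integrate to one
  for (cp in c(-0.2, 0.1, 0.45, 0.9, 1.3)) {
    total <- exp(confidence_log_density(0, cp, 0.2)) +
      stats::integrate(function(x) exp(confidence_log_density(x, cp, 0.2)),
                       0, 1, rel.tol = 1e-10)$value +
      exp(confidence_log_density(1, cp, 0.2))
    expect_equal(total, 1, tolerance = 1e-8)
  }
})

test_that("sessions respect learning-rate and relabeling symmetries", {
  trials <- random_trial_table(60, seed = 21)
  frozen <- model_params(alpha_w = 0, alpha_c = 0.4)
  out <- run_session(trials, frozen, mode = "conditioned")
  expect_true(all(out$w_cw_cw == frozen$w0_signal))
  expect_true(all(out$w_ccw_cw == frozen$w0_noise))

  # relabeling cw <-> ccw flips DV and swaps choice probabilities
  p <- model_params(alpha_w = 0.02, alpha_c = 0.4)
  mirrored <- trials
  mirrored$E_ccw <- trials$E_cw
  mirrored$E_cw <- trials$E_ccw
  mirrored$choice <- ifelse(trials$choice == "cw", "ccw", "cw")
  a <- run_session(trials, p, mode = "conditioned")
  b <- run_session(mirrored, p, mode = "conditioned")
  expect_equal(b$dv, -a$dv)
  expect_equal(b$certainty, a$certainty)
  expect_equal(b$p_cw, 1 - a$p_cw)

  # strong signal weights, clean energies, large beta: accuracy -> 1
  clean <- tibble::tibble(
    E_ccw = rep(c(1, 0), 50), E_cw = rep(c(0, 1), 50),
    true_orientation = rep(c("ccw", "cw"), 50))
  sharp <- model_params(alpha_w = 0, alpha_c = 0, beta = 50)
  gen <- run_session(clean, sharp, mode = "generative", seed = 4)
  expect_equal(mean(gen$correct), 1)
})

test_that("generative sessions are reproducible and expose the trajectory", {
  trials <- tibble::tibble(E_ccw = runif(40), E_cw = runif(40))
  p <- model_params(alpha_w = 0.05)
  a <- run_session(trials, p, mode = "generative", seed = 123)
  b <- run_session(trials, p, mode = "generative", seed = 123)
  expect_identical(a, b)
  expect_true(all(c("dv", "certainty", "cpe", "c_bar_pre") %in% names(a)))
  # logged prediction error uses the pre-update expected confidence
  expect_equal(a$cpe, a$confidence - a$c_bar_pre)
  # state carries over across chained sessions
  st <- attr(a, "state")
  cont <- run_session(trials, p, mode = "generative", seed = 9, state = st)
  expect_equal(cont$c_bar_pre[1], st$c_bar)
})
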