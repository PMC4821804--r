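# shared fixtures, built in code at test time

# a small noiseless Gabor stimulus image at a given contrast/orientation
noiseless_gabor <- function(cp = 100, theta = 20, ...) {
  spec <- stimulus_spec(peak_contrast_cp = cp, noise_contrast_cn = 0,
                        orientation_theta = theta, ...)
  compose_stimulus(make_gabor(spec), matrix(0, spec$grid_px, spec$grid_px),
                   spec)
}

# random conditioned-mode trial table (energies, choices, confidences)
random_trial_table <- function(n, seed) {
  withr::with_seed(seed, tibble::tibble(
    E_ccw = runif(n), E_cw = runif(n),
    choice = sample(c("cw", "ccw"), n, replace = TRUE),
    confidence = pmin(pmax(rnorm(n, 0.5, 0.3), 0), 1)
  ))
}

# brute-force conditioned-mode NLL from the scalar model primitives,
# recomputed trial by trial (the independent oracle for the C++ core)
brute_force_nll <- function(trials, params, c_bar0 = 0.5) {
  st <- model_state(params, c_bar0)
  ll <- 0
  for (t in seq_len(nrow(trials))) {
    A <- decision_activities(trials$E_ccw[t], trials$E_cw[t], st)
    dv <- decision_value(A[["A_ccw"]], A[["A_cw"]])
    p_cw <- choice_probability(dv, params$beta)
    ll <- ll + log(if (trials$choice[t] == "cw") p_cw else 1 - p_cw)
    ll <- ll + confidence_log_density(
      trials$confidence[t], decisional_certainty(dv, params$lambda),
      params$sigma_c)
    d <- confidence_prediction_error(trials$confidence[t], st$c_bar)
    A_ch <- if (trials$choice[t] == "cw") A[["A_cw"]] else A[["A_ccw"]]
    st <- update_weights(st, d, trials$E_ccw[t], trials$E_cw[t], A_ch,
                         trials$choice[t], params$alpha_w)
    st$c_bar <- update_expected_confidence(st$c_bar, d, params$alpha_c)
  }
  -ll
}

# a 9-run x 48-trial generative training session at the training contrast
training_session <- function(spec = observer_spec(), seed = 1) {
  sim <- simulate_fixed_contrast(spec, 8, 432, seed = seed)
  sim$run <- rep(1:9, each = 48)
  sim$signal <- (sim$w_ccw_ccw + sim$w_cw_cw) / 2
  sim$noise <- (sim$w_ccw_cw + sim$w_cw_ccw) / 2
  sim
}
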