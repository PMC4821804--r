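#' Parameters of the confidence-based learning model
#'
#' The five free parameters of the associative reinforcement-learning
#' model plus the initial connection weights:
#' * `alpha_w` — weight learning rate (>= 0); scales how strongly the
#'   confidence prediction error and the Hebbian co-activation move the
#'   sensory read-out weights.
#' * `alpha_c` — confidence learning rate in \[0, 1\]; the Rescorla-Wagner
#'   rate at which expected confidence tracks reported confidence.
#' * `beta` — softmax inverse temperature (>= 0) mapping the decision
#'   value onto choice probabilities.
#' * `lambda` — certainty scaling (>= 0); decisional certainty is
#'   `lambda * |DV|`.
#' * `sigma_c` — SD (> 0) of the censored-Gaussian noise linking
#'   decisional certainty to reported confidence.
#' * `w0_signal`, `w0_noise` — initial values of the signal weights
#'   (detector to same-orientation decision unit) and noise weights
#'   (detector to opposite-orientation unit).
#'
#' @param alpha_w,alpha_c,beta,lambda,sigma_c,w0_signal,w0_noise See above.
#' @return A `cl_model_params` object (named list).
#' @examples
#' model_params(alpha_w = 0.0018, alpha_c = 0.533)
#' @export
model_params <- function(alpha_w = 0.0018, alpha_c = 0.533, beta = 10,
                         lambda = 3, sigma_c = 0.2,
                         w0_signal = 0.5, w0_noise = 0.1) {
  assert_scalar_num(alpha_w, "alpha_w", 0)
  assert_scalar_num(alpha_c, "alpha_c", 0, 1)
  assert_scalar_num(beta, "beta", 0)
  assert_scalar_num(lambda, "lambda", 0)
  assert_scalar_num(sigma_c, "sigma_c", 0, strict_lower = TRUE)
  assert_scalar_num(w0_signal, "w0_signal")
  assert_scalar_num(w0_noise, "w0_noise")
  structure(list(alpha_w = alpha_w, alpha_c = alpha_c, beta = beta,
                 lambda = lambda, sigma_c = sigma_c,
                 w0_signal = w0_signal, w0_noise = w0_noise),
            class = "cl_model_params")
}

#' @export
print.cl_model_params <- function(x, ...) {
  cat("<model params> alpha_w = ", x$alpha_w, ", alpha_c = ", x$alpha_c,
      ", beta = ", x$beta, ", lambda = ", x$lambda, ", sigma_c = ",
      x$sigma_c, ", w0 = (", x$w0_signal, ", ", x$w0_noise, ")\n", sep = "")
  invisible(x)
}

#' Initial model state
#'
#' The evolving quantities of the model: the four read-out weights (two
#' signal, two noise) and the expected confidence `c_bar`, a running
#' average of past confidence reports.
#'
#' @param params A [model_params()] supplying the initial weights.
#' @param c_bar0 Initial expected confidence (default 0.5, mid-scale).
#' @return A `cl_model_state` (named list with `w_ccw_ccw`, `w_cw_cw`,
#'   `w_ccw_cw`, `w_cw_ccw`, `c_bar`).
#' @export
model_state <- function(params, c_bar0 = 0.5) {
  stopifnot(inherits(params, "cl_model_params"))
  assert_scalar_num(c_bar0, "c_bar0", 0, 1)
  structure(list(w_ccw_ccw = params$w0_signal, w_cw_cw = params$w0_signal,
                 w_ccw_cw = params$w0_noise, w_cw_ccw = params$w0_noise,
                 c_bar = c_bar0),
            class = "cl_model_state")
}

#' Decision-unit activities
#'
#' Weighted sums of the normalised orientation energies: each decision
#' unit pools the same-orientation detector through its signal weight and
#' the opposite-orientation detector through its noise weight:
#' `A_ccw = E_ccw * w_ccw_ccw + E_cw * w_cw_ccw` and
#' `A_cw  = E_cw * w_cw_cw  + E_ccw * w_ccw_cw`.
#'
#' @param E_ccw,E_cw Normalised orientation energies.
#' @param state A `cl_model_state`.
#' @return Named numeric vector `c(A_ccw = , A_cw = )`.
#' @export
decision_activities <- function(E_ccw, E_cw, state) {
  c(A_ccw = E_ccw * state$w_ccw_ccw + E_cw * state$w_cw_ccw,
    A_cw = E_cw * state$w_cw_cw + E_ccw * state$w_ccw_cw)
}

#' Decision value
#'
#' `DV = A_cw - A_ccw`; positive values favour a clockwise report.
#'
#' @param A_ccw,A_cw Decision-unit activities.
#' @return The decision value (scalar).
#' @export
decision_value <- function(A_ccw, A_cw) {
  unname(A_cw - A_ccw)
}

#' Softmax probability of a clockwise choice
#'
#' `p(cw) = 1 / (1 + exp(-beta * DV))`; overflow-guarded.
#'
#' @param DV Decision value.
#' @param beta Inverse temperature (>= 0).
#' @return Probability in (0, 1).
#' @export
choice_probability <- function(DV, beta) {
  stopifnot(beta >= 0)
  plogis(beta * DV)
}

#' Decisional certainty
#'
#' The model's internal confidence read-out, `c' = lambda * |DV|`.
#'
#' @param DV Decision value.
#' @param lambda Certainty scaling (>= 0).
#' @return Non-negative scalar.
#' @export
decisional_certainty <- function(DV, lambda) {
  stopifnot(lambda >= 0)
  lambda * abs(DV)
}

#' Confidence prediction error
#'
#' `delta = c - c_bar`: the mismatch between the confidence experienced on
#' this trial and the running estimate of expected confidence.  This is the
#' model's internally generated teaching signal.
#'
#' @param c_obs Reported confidence in \[0, 1\].
#' @param c_bar Expected confidence in \[0, 1\].
#' @return The prediction error, in \[-1, 1\].
#' @export
confidence_prediction_error <- function(c_obs, c_bar) {
  if (any(c_obs < 0 | c_obs > 1) || any(c_bar < 0 | c_bar > 1)) {
    abort("Confidence values must lie in [0, 1].")
  }
  c_obs - c_bar
}

#' Rescorla-Wagner update of expected confidence
#'
#' `c_bar <- c_bar + alpha_c * delta`.  With confidences in \[0, 1\] and
#' `alpha_c` in \[0, 1\] this is a convex combination, so `c_bar` can never
#' leave the unit interval.
#'
#' @param c_bar Current expected confidence.
#' @param delta Confidence prediction error.
#' @param alpha_c Confidence learning rate in \[0, 1\].
#' @return Updated expected confidence.
#' @export
update_expected_confidence <- function(c_bar, delta, alpha_c) {
  stopifnot(alpha_c >= 0, alpha_c <= 1)
  c_bar + alpha_c * delta
}

#' Associative (Hebbian x reinforcement) weight update
#'
#' A three-factor rule: each connection into the *chosen* decision unit
#' moves by `alpha_w * delta * E_pre * A_choice` — presynaptic energy times
#' postsynaptic activity, gated by the confidence prediction error.  The
#' two connections into the unchosen unit are untouched.
#'
#' @param state A `cl_model_state`.
#' @param delta Confidence prediction error for the trial.
#' @param E_ccw,E_cw Normalised energies of the trial.
#' @param A_choice Activity of the chosen decision unit.
#' @param choice `"cw"` or `"ccw"`.
#' @param alpha_w Weight learning rate (>= 0).
#' @return The updated `cl_model_state`.
#' @export
update_weights <- function(state, delta, E_ccw, E_cw, A_choice, choice,
                           alpha_w) {
  stopifnot(alpha_w >= 0, choice %in% c("cw", "ccw"))
  g <- alpha_w * delta * A_choice
  if (choice == "cw") {
    state$w_cw_cw <- state$w_cw_cw + g * E_cw
    state$w_ccw_cw <- state$w_ccw_cw + g * E_ccw
  } else {
    state$w_ccw_ccw <- state$w_ccw_ccw + g * E_ccw
    state$w_cw_ccw <- state$w_cw_ccw + g * E_cw
  }
  state
}

#' Censored-Gaussian log-likelihood of a confidence report
#'
#' Reported confidence is modelled as Gaussian around the decisional
#' certainty `c_prime` with SD `sigma_c`, censored at the ends of the
#' rating scale: interior reports contribute the normal log-density, a
#' report of exactly 0 contributes the log-mass below 0
#' (`log Phi((0 - c_prime)/sigma_c)`), and a report of exactly 1 the
#' log-mass above 1.  The three pieces integrate to 1.
#'
#' @param c_obs Reported confidence in \[0, 1\] (vectorised).
#' @param c_prime Decisional certainty.
#' @param sigma_c Report noise SD (> 0).
#' @return Log-density (interior) or log-mass (boundaries).
#' @export
confidence_log_density <- function(c_obs, c_prime, sigma_c) {
  if (any(sigma_c <= 0)) abort("`sigma_c` must be > 0.")
  if (any(c_obs < 0 | c_obs > 1)) abort("Confidence must lie in [0, 1].")
  out <- dnorm(c_obs, c_prime, sigma_c, log = TRUE)
  cp <- rep_len(c_prime, length(c_obs))
  sc <- rep_len(sigma_c, length(c_obs))
  lo <- which(c_obs == 0)
  hi <- which(c_obs == 1)
  if (length(lo)) out[lo] <- pnorm((0 - cp[lo]) / sc[lo], log.p = TRUE)
  if (length(hi)) {
    out[hi] <- pnorm((1 - cp[hi]) / sc[hi], lower.tail = FALSE, log.p = TRUE)
  }
  pmax(out, log(1e-300))
}
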