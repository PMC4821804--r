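# One model trial. `choice`/`confidence` NULL => generative sampling.
# Returns the per-trial record plus the updated state.
model_step <- function(state, E_ccw, E_cw, params, choice = NULL,
                       confidence = NULL,
                       update_order = "delta_first") {
  A <- decision_activities(E_ccw, E_cw, state)
  dv <- decision_value(A[["A_ccw"]], A[["A_cw"]])
  p_cw <- choice_probability(dv, params$beta)
  cert <- decisional_certainty(dv, params$lambda)
  if (is.null(choice)) {
    choice <- if (runif(1) < p_cw) "cw" else "ccw"
  }
  if (is.null(confidence)) {
    confidence <- min(max(rnorm(1, cert, params$sigma_c), 0), 1)
  }
  c_bar_pre <- state$c_bar
  if (update_order == "delta_first") {
    delta <- confidence_prediction_error(confidence, c_bar_pre)
    state <- update_weights(state, delta, E_ccw, E_cw,
                            if (choice == "cw") A[["A_cw"]] else A[["A_ccw"]], choice,
                            params$alpha_w)
    state$c_bar <- update_expected_confidence(state$c_bar, delta,
                                              params$alpha_c)
  } else {
    pre_delta <- confidence_prediction_error(confidence, c_bar_pre)
    state$c_bar <- update_expected_confidence(state$c_bar, pre_delta,
                                              params$alpha_c)
    delta <- confidence_prediction_error(confidence, state$c_bar)
    state <- update_weights(state, delta, E_ccw, E_cw,
                            if (choice == "cw") A[["A_cw"]] else A[["A_ccw"]], choice,
                            params$alpha_w)
  }
  list(choice = choice, confidence = confidence, p_cw = p_cw, dv = dv,
       certainty = cert, cpe = delta, c_bar_pre = c_bar_pre, state = state)
}

#' Run the learning model across a session of trials
#'
#' Plays the model through a stream of normalised orientation energies,
#' trial by trial.  In `"generative"` mode choices are sampled from the
#' softmax rule and confidence reports from the censored Gaussian around
#' decisional certainty; in `"conditioned"` mode the observed choices and
#' confidence reports in `trials` drive the updates (the convention used
#' when fitting the model to a participant).  Within each trial the order
#' is: activities, decision value, choice/confidence, confidence
#' prediction error against the pre-update expected confidence, weight
#' update, expected-confidence update.
#'
#' @param trials Data frame with normalised energies `E_ccw`, `E_cw`; for
#'   conditioned mode also `choice` (`"cw"`/`"ccw"`) and `confidence` in
#'   \[0, 1\].  An optional `true_orientation` column adds a `correct`
#'   column to the output.
#' @param params A [model_params()].
#' @param mode `"generative"` or `"conditioned"`.
#' @param c_bar0 Initial expected confidence (ignored when `state` given).
#' @param state Optional `cl_model_state` to continue from (e.g. across
#'   runs of a session; by default expected confidence and weights carry
#'   over seamlessly when you pass the state back in).
#' @param seed Optional integer seed for generative sampling.
#' @param update_order `"delta_first"` (default; prediction error computed
#'   against pre-update expected confidence, weights updated before the
#'   expected-confidence update) or `"cbar_first"`.
#' @return A tibble with one row per trial: energies, `p_cw`, `choice`,
#'   `confidence`, `correct` (if derivable), `dv`, `certainty`, `cpe`,
#'   `c_bar_pre` and the post-update weights.  The final model state is
#'   attached as attribute `"state"`.
#' @examples
#' trials <- tibble::tibble(E_ccw = runif(20), E_cw = runif(20))
#' run_session(trials, model_params(), mode = "generative", seed = 1)
#' @export
run_session <- function(trials, params, mode = c("generative", "conditioned"),
                        c_bar0 = 0.5, state = NULL, seed = NULL,
                        update_order = c("delta_first", "cbar_first")) {
  mode <- match.arg(mode)
  update_order <- match.arg(update_order)
  stopifnot(is.data.frame(trials), inherits(params, "cl_model_params"),
            all(c("E_ccw", "E_cw") %in% names(trials)))
  n <- nrow(trials)
  if (mode == "conditioned") {
    if (!all(c("choice", "confidence") %in% names(trials))) {
      abort("Conditioned mode needs observed `choice` and `confidence`.")
    }
    if (any(trials$confidence < 0 | trials$confidence > 1)) {
      abort("Observed confidence must lie in [0, 1].")
    }
  }
  if (is.null(state)) state <- model_state(params, c_bar0)
  run_one <- function() {
    p_cw <- dv <- certainty <- cpe <- c_bar_pre <- numeric(n)
    confidence <- numeric(n)
    choice <- character(n)
    W <- matrix(0, n, 4)
    for (t in seq_len(n)) {
      st <- model_step(
        state, trials$E_ccw[t], trials$E_cw[t], params,
        choice = if (mode == "conditioned") trials$choice[t],
        confidence = if (mode == "conditioned") trials$confidence[t],
        update_order = update_order
      )
      state <<- st$state
      p_cw[t] <- st$p_cw; choice[t] <- st$choice
      confidence[t] <- st$confidence; dv[t] <- st$dv
      certainty[t] <- st$certainty; cpe[t] <- st$cpe
      c_bar_pre[t] <- st$c_bar_pre
      W[t, ] <- c(state$w_ccw_ccw, state$w_cw_cw,
                  state$w_ccw_cw, state$w_cw_ccw)
    }
    tibble(trial = seq_len(n), E_ccw = trials$E_ccw, E_cw = trials$E_cw,
           p_cw = p_cw, choice = choice, confidence = confidence,
           dv = dv, certainty = certainty, cpe = cpe,
           c_bar_pre = c_bar_pre,
           w_ccw_ccw = W[, 1], w_cw_cw = W[, 2],
           w_ccw_cw = W[, 3], w_cw_ccw = W[, 4])
  }
  out <- if (mode == "generative") with_seed(seed, run_one()) else run_one()
  if ("true_orientation" %in% names(trials)) {
    out$true_orientation <- trials$true_orientation
    out$correct <- out$choice == trials$true_orientation
  }
  keep <- setdiff(names(trials),
                  c(names(out), "choice", "confidence"))
  for (nm in keep) out[[nm]] <- trials[[nm]]
  attr(out, "state") <- state
  out
}
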