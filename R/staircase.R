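#' Configure the two-phase adaptive contrast staircase
#'
#' The threshold procedure has two phases.  A coarse one-up-one-down phase
#' moves contrast by a fixed factor (`10^phase1_logstep`) down after each
#' correct and up after each incorrect response, to approach the threshold
#' range quickly.  After `switch_after_reversals` reversals it hands over
#' to a weighted one-up-two-down phase: contrast drops by `down_step`
#' percentage points after two consecutive correct responses and rises by
#' `down_step / down_up_ratio` after any error.  With
#' `down_up_ratio = 0.5488` the weighted phase converges where
#' `p^2 * step_down = (1 - p^2) * step_up`, i.e. at 80.35% correct (see
#' [equilibrium_performance()]).  The staircase terminates at the
#' `terminate_at_reversal`-th reversal (counted over both phases by
#' default).
#'
#' @param start_contrast Starting contrast, percent.
#' @param phase1_logstep Coarse-phase step, log10 units.
#' @param switch_after_reversals Reversals before switching to the
#'   weighted phase.
#' @param down_step Weighted-phase down step, contrast percentage points.
#' @param down_up_ratio Ratio of down step to up step.
#' @param terminate_at_reversal Total reversal count that terminates the
#'   staircase; `Inf` for a free-running (continuously adaptive)
#'   staircase.
#' @param contrast_bounds Two-element vector of contrast limits, percent.
#' @param start_phase `"coarse"` or `"weighted"`; continuously adaptive
#'   procedures that begin at a known threshold start directly weighted.
#' @param reset_reversals_at_switch If `TRUE`, the reversal count used for
#'   termination restarts at the phase switch.
#' @return A `cl_staircase_config`.
#' @export
staircase_config <- function(start_contrast = 20,
                             phase1_logstep = 0.05,
                             switch_after_reversals = 3,
                             down_step = 0.33,
                             down_up_ratio = 0.5488,
                             terminate_at_reversal = 9,
                             contrast_bounds = c(0.1, 100),
                             start_phase = c("coarse", "weighted"),
                             reset_reversals_at_switch = FALSE) {
  assert_scalar_num(start_contrast, "start_contrast", 0, strict_lower = TRUE)
  assert_scalar_num(phase1_logstep, "phase1_logstep", 0, strict_lower = TRUE)
  assert_scalar_num(switch_after_reversals, "switch_after_reversals", 0)
  assert_scalar_num(down_step, "down_step", 0, strict_lower = TRUE)
  assert_scalar_num(down_up_ratio, "down_up_ratio", 0, strict_lower = TRUE)
  stopifnot(length(contrast_bounds) == 2, contrast_bounds[1] > 0,
            diff(contrast_bounds) > 0)
  assert_flag(reset_reversals_at_switch, "reset_reversals_at_switch")
  structure(list(
    start_contrast = start_contrast,
    phase1_logstep = phase1_logstep,
    switch_after_reversals = switch_after_reversals,
    down_step = down_step,
    down_up_ratio = down_up_ratio,
    up_step = down_step / down_up_ratio,
    terminate_at_reversal = terminate_at_reversal,
    contrast_bounds = contrast_bounds,
    start_phase = match.arg(start_phase),
    reset_reversals_at_switch = reset_reversals_at_switch
  ), class = "cl_staircase_config")
}

#' Initialise a staircase state
#'
#' @param cfg A [staircase_config()].
#' @param contrast Optional starting contrast overriding the config (e.g.
#'   a previously determined threshold).
#' @return A `cl_staircase_state`: phase, current contrast, consecutive
#'   correct counter, reversal history (with phase tags), last movement
#'   direction and termination flag.
#' @export
staircase_init <- function(cfg, contrast = NULL) {
  stopifnot(inherits(cfg, "cl_staircase_config"))
  structure(list(
    phase = cfg$start_phase,
    contrast = if (is.null(contrast)) cfg$start_contrast else contrast,
    consecutive_correct = 0L,
    reversal_contrasts = numeric(0),
    reversal_phases = character(0),
    n_reversals = 0L,
    last_direction = "none",
    terminated = FALSE
  ), class = "cl_staircase_state")
}

#' Advance a staircase by one response
#'
#' Applies the current phase's rule, records reversals (changes of
#' movement direction), switches phase after the configured reversal
#' count, terminates at the termination reversal, and clips contrast to
#' its bounds.  In the weighted phase the consecutive-correct counter
#' resets on every down step and on every error.
#'
#' @param state A `cl_staircase_state`.
#' @param correct Logical: was the response correct?
#' @param cfg The [staircase_config()].
#' @return The updated `cl_staircase_state`.
#' @export
staircase_update <- function(state, correct, cfg) {
  if (state$terminated) abort("Staircase already terminated.")
  move <- "none"
  if (state$phase == "coarse") {
    if (correct) {
      state$contrast <- state$contrast * 10^(-cfg$phase1_logstep)
      move <- "down"
    } else {
      state$contrast <- state$contrast * 10^(cfg$phase1_logstep)
      move <- "up"
    }
  } else {
    if (correct) {
      state$consecutive_correct <- state$consecutive_correct + 1L
      if (state$consecutive_correct >= 2L) {
        state$contrast <- state$contrast - cfg$down_step
        state$consecutive_correct <- 0L
        move <- "down"
      }
    } else {
      state$consecutive_correct <- 0L
      state$contrast <- state$contrast + cfg$up_step
      move <- "up"
    }
  }
  state$contrast <- min(max(state$contrast, cfg$contrast_bounds[1]),
                        cfg$contrast_bounds[2])
  if (move != "none") {
    if (state$last_direction != "none" && move != state$last_direction) {
      state$n_reversals <- state$n_reversals + 1L
      state$reversal_contrasts <- c(state$reversal_contrasts, state$contrast)
      state$reversal_phases <- c(state$reversal_phases, state$phase)
      if (state$phase == "coarse" &&
          state$n_reversals >= cfg$switch_after_reversals) {
        state$phase <- "weighted"
        state$consecutive_correct <- 0L
        if (cfg$reset_reversals_at_switch) state$n_reversals <- 0L
      }
      if (state$n_reversals >= cfg$terminate_at_reversal) {
        state$terminated <- TRUE
      }
    }
    state$last_direction <- move
  }
  state
}

#' Convergence performance of a weighted up-down staircase
#'
#' At equilibrium the expected downward and upward movement balance:
#' `p^n_down * step_down = (1 - p^n_down) * step_up`, giving
#' `p = (1 / (1 + ratio))^(1 / n_down)` where `ratio = step_down/step_up`.
#' For the task's ratio of 0.5488 with the one-up-two-down rule this is
#' 0.80353 — the 80.35%-correct convergence point of the threshold
#' procedure.
#'
#' @param down_up_ratio Ratio of down-step to up-step sizes (> 0).
#' @param n_down Number of consecutive correct responses required for a
#'   down step.
#' @return Proportion correct at convergence.
#' @examples
#' equilibrium_performance(0.5488, 2)  # 0.80353
#' @export
equilibrium_performance <- function(down_up_ratio, n_down = 2) {
  assert_scalar_num(down_up_ratio, "down_up_ratio", 0, strict_lower = TRUE)
  assert_scalar_num(n_down, "n_down", 1)
  (1 / (1 + down_up_ratio))^(1 / n_down)
}

#' Step ratio achieving a target convergence performance
#'
#' Inverts [equilibrium_performance()]: the down/up step-size ratio at
#' which a weighted `n_down`-down staircase converges at proportion
#' correct `p` is `(1 - p^n_down) / p^n_down`.
#'
#' @param p Target proportion correct at convergence, in (0, 1).
#' @param n_down Consecutive correct responses required for a down step.
#' @return The down/up step-size ratio.
#' @examples
#' equilibrium_ratio(0.8035, 2)
#' @export
equilibrium_ratio <- function(p, n_down = 2) {
  assert_scalar_num(p, "p", 0, 1)
  if (p <= 0 || p >= 1) abort("`p` must lie strictly between 0 and 1.")
  (1 - p^n_down) / p^n_down
}

#' Threshold estimate from a terminated staircase
#'
#' The mean of the reversal contrasts recorded during the weighted
#' (fine-tuning) phase.
#'
#' @param state A terminated `cl_staircase_state` (or any state with at
#'   least one weighted-phase reversal).
#' @return Contrast threshold, percent.
#' @export
threshold_estimate <- function(state) {
  idx <- state$reversal_phases == "weighted"
  if (!any(idx)) abort("No weighted-phase reversals to average.")
  mean(state$reversal_contrasts[idx])
}

#' Run one staircase against an observer
#'
#' Drives a single staircase with responses drawn from `observer`, a
#' function mapping contrast (percent) to the probability of a correct
#' response.  Runs until the staircase terminates, or for exactly
#' `n_trials` if given (ignoring termination — used to study the
#' procedure's stationary behaviour).
#'
#' @param observer `function(contrast) -> p(correct)`.
#' @param cfg A [staircase_config()].
#' @param n_trials Fixed number of trials, or `NULL` to run to
#'   termination.
#' @param max_trials Safety cap when running to termination.
#' @param seed Optional integer seed.
#' @return A list with `log` (tibble: trial, contrast, correct, phase,
#'   reversal flag) and `state` (final `cl_staircase_state`).
#' @export
run_staircase <- function(observer, cfg, n_trials = NULL,
                          max_trials = 10000, seed = NULL) {
  stopifnot(is.function(observer), inherits(cfg, "cl_staircase_config"))
  with_seed(seed, {
    state <- staircase_init(cfg)
    cap <- if (is.null(n_trials)) max_trials else n_trials
    contrast <- numeric(cap); correct <- logical(cap)
    phase <- character(cap); rev_flag <- logical(cap)
    t <- 0L
    while (t < cap && !(is.null(n_trials) && state$terminated)) {
      t <- t + 1L
      contrast[t] <- state$contrast
      phase[t] <- state$phase
      correct[t] <- runif(1) < observer(state$contrast)
      n_rev_before <- state$n_reversals
      if (state$terminated) {
        # fixed-length mode: keep stepping a fresh copy of the rule
        state$terminated <- FALSE
      }
      state <- staircase_update(state, correct[t], cfg)
      rev_flag[t] <- state$n_reversals > n_rev_before
    }
    if (is.null(n_trials) && !state$terminated) {
      warn("Staircase did not terminate within `max_trials`.")
    }
    list(log = tibble(trial = seq_len(t), contrast = contrast[seq_len(t)],
                      correct = correct[seq_len(t)], phase = phase[seq_len(t)],
                      reversal = rev_flag[seq_len(t)]),
         state = state)
  })
}

#' Run a blocked test session with alternating reference axes
#'
#' Emulates a threshold test session: one independent staircase per
#' reference axis, interleaved in blocks of `block_size` trials with the
#' axis alternating between blocks, until each staircase reaches its
#' termination reversal.  Once one axis has terminated, remaining blocks
#' run on the other axis alone.
#'
#' @param observer `function(contrast, axis) -> p(correct)` (an
#'   axis-blind `function(contrast)` is also accepted).
#' @param cfg A [staircase_config()].
#' @param block_size Trials per block.
#' @param axes Names of the two reference axes; the first axis runs first.
#' @param start_contrasts Optional named starting contrasts per axis.
#' @param max_trials Per-axis safety cap.
#' @param seed Optional integer seed.
#' @return A list with `thresholds` (tibble: axis, threshold, n_trials)
#'   and `log` (tibble with block, axis, trial, contrast, correct, phase,
#'   reversal).
#' @export
run_staircase_session <- function(observer, cfg, block_size = 16,
                                  axes = c("vertical", "horizontal"),
                                  start_contrasts = NULL,
                                  max_trials = 10000, seed = NULL) {
  stopifnot(is.function(observer), inherits(cfg, "cl_staircase_config"),
            length(axes) == 2)
  obs <- if (length(formals(observer)) >= 2) observer else {
    function(contrast, axis) observer(contrast)
  }
  with_seed(seed, {
    states <- lapply(axes, function(a) {
      staircase_init(cfg, contrast = start_contrasts[[a]])
    })
    names(states) <- axes
    counts <- setNames(c(0L, 0L), axes)
    logs <- list()
    block <- 0L
    repeat {
      live <- axes[!vapply(states, `[[`, TRUE, "terminated")]
      if (length(live) == 0) break
      block <- block + 1L
      axis <- if (length(live) == 2) live[(block - 1L) %% 2L + 1L] else live
      st <- states[[axis]]
      for (k in seq_len(block_size)) {
        if (st$terminated) break
        counts[axis] <- counts[axis] + 1L
        ctr <- st$contrast
        ph <- st$phase
        corr <- runif(1) < obs(ctr, axis)
        nrev <- st$n_reversals
        st <- staircase_update(st, corr, cfg)
        logs[[length(logs) + 1L]] <-
          tibble(block = block, axis = axis, trial = counts[[axis]],
                 contrast = ctr, correct = corr, phase = ph,
                 reversal = st$n_reversals > nrev)
      }
      states[[axis]] <- st
      if (any(counts > max_trials)) {
        warn("Axis exceeded `max_trials` without terminating; stopping.")
        break
      }
    }
    thresholds <- purrr::map_df(axes, function(a) {
      tibble(axis = a,
             threshold = threshold_estimate(states[[a]]),
             n_trials = counts[[a]])
    })
    list(thresholds = thresholds, log = bind_rows(logs), states = states)
  })
}

#' A logistic psychometric observer
#'
#' Returns `function(contrast) -> p(correct)` of the form
#' `guess + (1 - guess - lapse) * plogis((contrast - threshold) / spread)`,
#' the standard logistic psychometric function for a two-alternative
#' orientation judgement (chance level `guess = 0.5`).
#'
#' @param threshold Contrast (percent) at the function's midpoint.
#' @param spread Logistic scale, contrast percentage points.
#' @param guess Lower asymptote (chance performance).
#' @param lapse Lapse rate shrinking the upper asymptote.
#' @return A function of contrast.
#' @examples
#' obs <- logistic_observer(8, 2)
#' obs(8)   # 0.75
#' @export
logistic_observer <- function(threshold, spread, guess = 0.5, lapse = 0) {
  assert_scalar_num(threshold, "threshold", 0)
  assert_scalar_num(spread, "spread", 0, strict_lower = TRUE)
  function(contrast) {
    guess + (1 - guess - lapse) * plogis((contrast - threshold) / spread)
  }
}
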