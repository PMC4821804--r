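#' Specify a synthetic observer
#'
#' A statistical surrogate for a participant: trial-wise orientation
#' energies are drawn from a rectified-Gaussian model that is linear in
#' stimulus contrast — designated-orientation raw energy
#' `~ max(0, Normal(energy_floor + energy_gain * c_p, energy_noise_sd))`,
#' opposite-orientation raw energy `~ max(0, Normal(energy_floor,
#' energy_noise_sd))` — and choices and confidence reports are generated
#' by the confidence-guided learning model itself ([run_session()]
#' machinery) with parameters `true_params`.
#'
#' Raw energies are mapped to the model's normalised scale by the fixed
#' constant `energy_norm`, a stand-in for the participant-wise maximum
#' used when fitting: the default was calibrated once as the expected
#' session maximum of a 432-trial stream at the 8%-contrast training
#' regime, so generative and fitted energy scales agree closely.  The
#' default `energy_gain` was calibrated by bisection
#' ([calibrate_energy_gain()]) so the default observer scores about 80%
#' correct at 8% contrast — the contrast regime the threshold procedure
#' holds participants at.
#'
#' @param true_params A [model_params()]: the generating parameters.
#' @param energy_gain Designated-energy slope per contrast percentage
#'   point (>= 0).
#' @param energy_floor Baseline mean energy for both orientations.
#' @param energy_noise_sd Trial-to-trial energy SD.
#' @param energy_norm Fixed normalisation constant for generative mode.
#' @return A `cl_observer_spec`.
#' @export
observer_spec <- function(true_params = model_params(),
                          energy_gain = 0.0525,
                          energy_floor = 0.2,
                          energy_noise_sd = 0.15,
                          energy_norm = 1.067) {
  stopifnot(inherits(true_params, "cl_model_params"))
  if (energy_gain < 0) abort("`energy_gain` must be non-negative.")
  assert_scalar_num(energy_floor, "energy_floor", 0)
  assert_scalar_num(energy_noise_sd, "energy_noise_sd", 0,
                    strict_lower = TRUE)
  assert_scalar_num(energy_norm, "energy_norm", 0, strict_lower = TRUE)
  structure(list(true_params = true_params, energy_gain = energy_gain,
                 energy_floor = energy_floor,
                 energy_noise_sd = energy_noise_sd,
                 energy_norm = energy_norm),
            class = "cl_observer_spec")
}

#' Specify the experiment layout
#'
#' The study design the generator emulates: a pre-test threshold session
#' (both reference axes, blocks of `test_block_size` trials), an
#' adjustment run, `n_training_runs` training runs of `trials_per_run`
#' trials on the trained axis — a staircase-controlled condition holding
#' performance at the weighted staircase's convergence point, interleaved
#' trial-by-trial with a constant-contrast condition on
#' `constant_condition_fraction` of the trials — and a post-test.  Trial
#' timing: a fixation interval of 2000 +/- 1000 ms precedes the 100 ms
#' stimulus, followed by 2000 +/- 1000 ms before the confidence cue
#' (uniform jitter).
#'
#' @param n_training_runs Number of training runs.
#' @param trials_per_run Trials per training run.
#' @param constant_condition_fraction Fraction of training trials at
#'   constant contrast.
#' @param trained_axis `"vertical"` or `"horizontal"`.
#' @param test_block_size Trials per test-session block.
#' @param test_staircase [staircase_config()] for the test sessions.
#' @param training_staircase [staircase_config()] for the adjustment and
#'   training runs (free-running weighted staircase by default).
#' @param fixation_ms,fixation_jitter_ms,poststim_ms,poststim_jitter_ms
#'   Event timing means and (uniform) half-ranges, milliseconds.
#' @return A `cl_experiment_design`.
#' @export
experiment_design <- function(n_training_runs = 9,
                              trials_per_run = 48,
                              constant_condition_fraction = 0.5,
                              trained_axis = c("vertical", "horizontal"),
                              test_block_size = 16,
                              test_staircase = staircase_config(),
                              training_staircase =
                                staircase_config(start_phase = "weighted",
                                                 terminate_at_reversal = Inf),
                              fixation_ms = 2000, fixation_jitter_ms = 1000,
                              poststim_ms = 2000, poststim_jitter_ms = 1000) {
  trained_axis <- match.arg(trained_axis)
  stopifnot(n_training_runs >= 1, trials_per_run >= 2,
            constant_condition_fraction >= 0,
            constant_condition_fraction <= 1)
  structure(list(
    n_training_runs = n_training_runs, trials_per_run = trials_per_run,
    constant_condition_fraction = constant_condition_fraction,
    trained_axis = trained_axis,
    untrained_axis = setdiff(c("vertical", "horizontal"), trained_axis),
    test_block_size = test_block_size,
    test_staircase = test_staircase,
    training_staircase = training_staircase,
    fixation_ms = fixation_ms, fixation_jitter_ms = fixation_jitter_ms,
    poststim_ms = poststim_ms, poststim_jitter_ms = poststim_jitter_ms
  ), class = "cl_experiment_design")
}

# raw surrogate energies for one batch of trials (uses the ambient RNG)
draw_energies <- function(contrasts, true_orientations, spec) {
  n <- length(contrasts)
  des <- pmax(0, rnorm(n, spec$energy_floor +
                         spec$energy_gain * contrasts,
                       spec$energy_noise_sd))
  opp <- pmax(0, rnorm(n, spec$energy_floor, spec$energy_noise_sd))
  cw <- true_orientations == "cw"
  tibble(contrast = contrasts, true_orientation = true_orientations,
         E_cw_raw = ifelse(cw, des, opp),
         E_ccw_raw = ifelse(cw, opp, des))
}

#' Generate a surrogate energy stream
#'
#' Draws independent trial-wise raw orientation energies from the
#' observer's rectified-Gaussian surrogate and adds normalised energies
#' using the observer's fixed calibration constant.
#'
#' @param contrasts Stimulus contrasts, percent.
#' @param true_orientations `"cw"`/`"ccw"` per trial.
#' @param spec An [observer_spec()].
#' @param seed Optional integer seed (same seed, same stream).
#' @return A tibble with `contrast`, `true_orientation`, `E_ccw_raw`,
#'   `E_cw_raw`, `E_ccw`, `E_cw`.
#' @export
generate_energy_stream <- function(contrasts, true_orientations, spec,
                                   seed = NULL) {
  stopifnot(inherits(spec, "cl_observer_spec"),
            length(contrasts) == length(true_orientations),
            all(true_orientations %in% c("cw", "ccw")))
  out <- with_seed(seed, draw_energies(contrasts, true_orientations, spec))
  normalize_energies(out, mode = "fixed", k = spec$energy_norm)
}

#' Calibrate the surrogate energy gain to a target accuracy
#'
#' Bisection on the simulated proportion correct of a non-learning copy
#' of the observer (weights held at their initial values) at a reference
#' contrast: returns the `energy_gain` at which accuracy matches
#' `target`, the staircase convergence performance by default.
#'
#' @param spec An [observer_spec()] (its gain is ignored).
#' @param target Target proportion correct.
#' @param contrast Reference contrast, percent.
#' @param n_trials Simulated trials per bisection step.
#' @param gain_range Search interval for the gain.
#' @param tol Bisection tolerance on the gain.
#' @param seed Integer seed (common random numbers across steps).
#' @return The calibrated gain (scalar).
#' @export
calibrate_energy_gain <- function(spec, target = 0.8035, contrast = 8,
                                  n_trials = 5000,
                                  gain_range = c(0, 0.5), tol = 1e-4,
                                  seed = 1) {
  stopifnot(inherits(spec, "cl_observer_spec"))
  seeds <- derive_seeds(seed, 3L)  # common random numbers across steps
  acc_at <- function(gain) {
    s <- spec
    s$energy_gain <- gain
    mean(vapply(seeds, function(sd_) {
      mean(simulate_fixed_contrast(s, contrast, n_trials, seed = sd_,
                                   learning = FALSE)$correct)
    }, 0))
  }
  lo <- gain_range[1]; hi <- gain_range[2]
  if (acc_at(hi) < target) abort("`gain_range` upper end too low.")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (acc_at(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate trials at a fixed contrast
#'
#' Runs the observer's generating model over `n_trials` trials at one
#' contrast (orientations drawn equiprobably), optionally with learning
#' disabled (weights pinned at their initial values).
#'
#' @param spec An [observer_spec()].
#' @param contrast Contrast, percent.
#' @param n_trials Number of trials.
#' @param seed Optional integer seed.
#' @param learning If `FALSE`, `alpha_w` and `alpha_c` are set to 0.
#' @return The [run_session()] trial tibble (with `correct`).
#' @export
simulate_fixed_contrast <- function(spec, contrast, n_trials, seed = NULL,
                                    learning = TRUE) {
  stopifnot(inherits(spec, "cl_observer_spec"))
  params <- spec$true_params
  if (!learning) {
    params <- model_params(0, 0, params$beta, params$lambda,
                           params$sigma_c, params$w0_signal,
                           params$w0_noise)
  }
  with_seed(seed, {
    ori <- sample(c("cw", "ccw"), n_trials, replace = TRUE)
    stream <- generate_energy_stream(rep(contrast, n_trials), ori, spec)
    run_session(stream, params, mode = "generative")
  })
}

# one generative model trial of the synthetic observer (ambient RNG)
observer_trial <- function(state, contrast, orientation, spec) {
  e <- draw_energies(contrast, orientation, spec)
  E_ccw <- e$E_ccw_raw / spec$energy_norm
  E_cw <- e$E_cw_raw / spec$energy_norm
  st <- model_step(state, E_ccw, E_cw, spec$true_params)
  c(list(E_ccw_raw = e$E_ccw_raw, E_cw_raw = e$E_cw_raw,
         E_ccw = E_ccw, E_cw = E_cw, true_orientation = orientation,
         contrast = contrast, correct = st$choice == orientation), st)
}

#' Simulate the full experiment for one synthetic observer
#'
#' Assembles the complete session structure: pre-test threshold
#' staircases on both reference axes (blocked, axes alternating), an
#' adjustment run that fine-tunes contrast starting from the pre-test
#' threshold, training runs with the staircase-controlled condition
#' interleaved with the constant-contrast control condition, and a
#' post-test.  Choices and confidence reports always come from the
#' generating model with learning on; the model keeps separate read-out
#' weights per reference axis (learning is axis-specific) while expected
#' confidence is carried across the whole experiment.  The constant
#' condition's contrast is fixed at the staircase contrast reached at the
#' end of the adjustment run.
#'
#' @param spec An [observer_spec()].
#' @param design An [experiment_design()].
#' @param seed Integer seed; the full dataset is bit-reproducible from
#'   `(spec, design, seed)`.
#' @return A list of class `cl_experiment`:
#'   * `trials` — tibble of every trial (test and training) with model
#'     variables, condition tags, run indices and event times (seconds,
#'     per run);
#'   * `thresholds` — tibble with pre/post threshold per axis;
#'   * `final_state` — per-axis model states after the post-test.
#' @export
simulate_experiment <- function(spec, design = experiment_design(),
                                seed = 1) {
  stopifnot(inherits(spec, "cl_observer_spec"),
            inherits(design, "cl_experiment_design"))
  with_seed(seed, {
    env <- new.env()
    env$states <- list(vertical = model_state(spec$true_params),
                       horizontal = model_state(spec$true_params))
    env$rows <- list()

    sync_cbar <- function(axis) {
      other <- setdiff(c("vertical", "horizontal"), axis)
      env$states[[other]]$c_bar <- env$states[[axis]]$c_bar
    }
    record <- function(session, run, block, trial, axis, condition, tr,
                       t_trial = NA_real_, t_stim = NA_real_) {
      st <- tr$state
      env$rows[[length(env$rows) + 1L]] <- tibble(
        session = session, run = run, block = block, trial = trial,
        axis = axis, condition = condition,
        true_orientation = tr$true_orientation, contrast = tr$contrast,
        E_ccw_raw = tr$E_ccw_raw, E_cw_raw = tr$E_cw_raw,
        E_ccw = tr$E_ccw, E_cw = tr$E_cw, p_cw = tr$p_cw,
        choice = tr$choice, confidence = tr$confidence,
        correct = tr$correct, dv = tr$dv, certainty = tr$certainty,
        cpe = tr$cpe, c_bar_pre = tr$c_bar_pre,
        w_ccw_ccw = st$w_ccw_ccw, w_cw_cw = st$w_cw_cw,
        w_ccw_cw = st$w_ccw_cw, w_cw_ccw = st$w_cw_ccw,
        t_trial_onset = t_trial, t_stimulus_onset = t_stim
      )
    }

    run_test <- function(session) {
      cfg <- design$test_staircase
      axes <- c(design$trained_axis, design$untrained_axis)
      scs <- lapply(axes, function(a) staircase_init(cfg))
      names(scs) <- axes
      counts <- setNames(c(0L, 0L), axes)
      block <- 0L
      repeat {
        live <- axes[!vapply(scs, `[[`, TRUE, "terminated")]
        if (length(live) == 0) break
        block <- block + 1L
        axis <- if (length(live) == 2) live[(block - 1L) %% 2L + 1L] else live
        for (k in seq_len(design$test_block_size)) {
          if (scs[[axis]]$terminated) break
          counts[axis] <- counts[axis] + 1L
          ori <- sample(c("cw", "ccw"), 1)
          tr <- observer_trial(env$states[[axis]], scs[[axis]]$contrast,
                               ori, spec)
          env$states[[axis]] <- tr$state
          sync_cbar(axis)
          scs[[axis]] <- staircase_update(scs[[axis]], tr$correct, cfg)
          record(session, NA_integer_, block, counts[[axis]], axis,
                 "test", tr)
        }
        if (any(counts > 5000L)) {
          abort("Test staircase failed to terminate within 5000 trials.")
        }
      }
      purrr::map_df(axes, function(a) {
        tibble(session = session, axis = a,
               threshold = threshold_estimate(scs[[a]]),
               n_trials = counts[[a]])
      })
    }

    draw_times <- function(n) {
      fix <- runif(n, design$fixation_ms - design$fixation_jitter_ms,
                   design$fixation_ms + design$fixation_jitter_ms) / 1000
      post <- runif(n, design$poststim_ms - design$poststim_jitter_ms,
                    design$poststim_ms + design$poststim_jitter_ms) / 1000
      resp <- 0.75 + stats::rlnorm(n, log(2.47), 0.3) + 1
      dur <- fix + 0.1 + post + resp
      onset <- c(0, cumsum(dur[-n]))
      list(trial = onset, stim = onset + fix)
    }

    run_training <- function(run, sc, constant_contrast) {
      n <- design$trials_per_run
      n_const <- round(design$constant_condition_fraction * n)
      cond <- sample(c(rep("constant", n_const),
                       rep("staircase", n - n_const)))
      tm <- draw_times(n)
      axis <- design$trained_axis
      for (t in seq_len(n)) {
        ori <- sample(c("cw", "ccw"), 1)
        ctr <- if (cond[t] == "constant") constant_contrast else sc$contrast
        tr <- observer_trial(env$states[[axis]], ctr, ori, spec)
        env$states[[axis]] <- tr$state
        sync_cbar(axis)
        if (cond[t] == "staircase") {
          sc <- staircase_update(sc, tr$correct, design$training_staircase)
        }
        record("training", run, NA_integer_, t, axis, cond[t], tr,
               tm$trial[t], tm$stim[t])
      }
      sc
    }

    thr_pre <- run_test("pre_test")

    # adjustment run: all-staircase, starting at the pre-test threshold
    pre_thr <- thr_pre$threshold[thr_pre$axis == design$trained_axis]
    sc <- staircase_init(design$training_staircase, contrast = pre_thr)
    tm <- draw_times(design$trials_per_run)
    for (t in seq_len(design$trials_per_run)) {
      ori <- sample(c("cw", "ccw"), 1)
      tr <- observer_trial(env$states[[design$trained_axis]], sc$contrast,
                           ori, spec)
      env$states[[design$trained_axis]] <- tr$state
      sync_cbar(design$trained_axis)
      sc <- staircase_update(sc, tr$correct, design$training_staircase)
      record("adjustment", 0L, NA_integer_, t, design$trained_axis,
             "staircase", tr, tm$trial[t], tm$stim[t])
    }
    constant_contrast <- sc$contrast

    for (r in seq_len(design$n_training_runs)) {
      sc <- run_training(r, sc, constant_contrast)
    }

    thr_post <- run_test("post_test")

    structure(list(
      trials = bind_rows(env$rows),
      thresholds = bind_rows(thr_pre, thr_post),
      final_state = env$states,
      spec = spec, design = design, seed = seed
    ), class = "cl_experiment")
  })
}

#' @export
print.cl_experiment <- function(x, ...) {
  cat("<experiment> ", nrow(x$trials), " trials (",
      sum(x$trials$session == "training"), " training); trained axis: ",
      x$design$trained_axis, "\n", sep = "")
  print(x$thresholds)
  invisible(x)
}
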