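#' Canonical double-gamma hemodynamic response function
#'
#' The standard two-gamma impulse response: a response gamma peaking at
#' `peak_delay` seconds minus an undershoot gamma peaking at
#' `undershoot_delay` seconds, weighted `1 : 1/ratio`, scaled to unit
#' peak.  With the default parameters (peak 6 s, undershoot 16 s,
#' dispersions 1, ratio 6) the response maximum sits about 5 s after the
#' driving event.
#'
#' @param t Time points, seconds (non-negative part of the support).
#' @param peak_delay,undershoot_delay Gamma shape parameters (seconds).
#' @param peak_disp,undershoot_disp Gamma dispersions.
#' @param ratio Peak-to-undershoot amplitude ratio.
#' @return HRF values at `t`, unit peak.
#' @export
hrf_double_gamma <- function(t, peak_delay = 6, undershoot_delay = 16,
                             peak_disp = 1, undershoot_disp = 1,
                             ratio = 6) {
  h <- dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    dgamma(t, shape = undershoot_delay / undershoot_disp,
           scale = undershoot_disp) / ratio
  h[t < 0] <- 0
  m <- max(h)
  if (m > 0) h <- h / m
  h
}

#' Simulate the striatal BOLD response of a learning trial
#'
#' Builds a punctate neural activation vector on a 10 Hz grid spanning
#' -4 s to +20 s around stimulus onset: +1 at the trial onset (t = -2 s),
#' the anticipatory confidence signal, and +1 / 0 / -1 at stimulus onset
#' (t = 0 s) for a positive, absent or negative confidence prediction
#' error.  The vector is convolved with the canonical double-gamma HRF
#' and truncated to the 240-sample window.
#'
#' @param scenario `"positive_pe"`, `"absent_pe"` or `"negative_pe"`.
#' @param anticipation Amplitude of the trial-onset impulse.
#' @param hrf_args Named list of overrides for [hrf_double_gamma()].
#' @return A `cl_bold` tibble with 240 rows: `time` (seconds relative to
#'   stimulus onset) and `bold`.
#' @export
simulate_bold <- function(scenario = c("positive_pe", "absent_pe",
                                       "negative_pe"),
                          anticipation = 1, hrf_args = list()) {
  scenario <- match.arg(scenario)
  fs <- 10
  time <- seq(-4, 20 - 1 / fs, by = 1 / fs)  # 240 samples
  neural <- numeric(length(time))
  neural[which.min(abs(time - (-2)))] <- anticipation
  pe <- switch(scenario, positive_pe = 1, absent_pe = 0, negative_pe = -1)
  neural[which.min(abs(time - 0))] <- neural[which.min(abs(time - 0))] + pe
  hrf <- do.call(hrf_double_gamma,
                 c(list(t = seq(0, 32, by = 1 / fs)), hrf_args))
  bold <- convolve_truncate(neural, hrf)
  out <- tibble(time = time, bold = bold)
  class(out) <- c("cl_bold", class(out))
  attr(out, "scenario") <- scenario
  out
}

# causal linear convolution truncated to the length of `x`
convolve_truncate <- function(x, kernel) {
  full <- convolve(x, rev(kernel), type = "open")
  full[seq_along(x)]
}

#' Build HRF-convolved parametric regressors from a model trajectory
#'
#' Constructs the two model-based regressors of the learning analysis:
#' the trial-onset impulse train modulated by expected confidence
#' (`c_bar_pre`) and the stimulus-onset train modulated by the confidence
#' prediction error (`cpe`).  Modulators are mean-centred across trials,
#' placed as impulses on a fine time grid at their event onsets,
#' convolved with the canonical double-gamma HRF, and sampled at the
#' scanner repetition time.
#'
#' @param trajectory Data frame with `c_bar_pre`, `cpe`, `t_trial_onset`
#'   and `t_stimulus_onset` (seconds).
#' @param TR Sampling interval, seconds.
#' @param duration Total run duration, seconds; defaults to the last
#'   event plus 30 s.  Events beyond `duration` are an error.
#' @param dt Internal convolution grid, seconds.
#' @param hrf_args Named list of overrides for [hrf_double_gamma()].
#' @return A tibble: `time`, `expected_confidence`, `cpe`.
#' @export
build_parametric_regressors <- function(trajectory, TR = 2,
                                        duration = NULL, dt = 0.1,
                                        hrf_args = list()) {
  need <- c("c_bar_pre", "cpe", "t_trial_onset", "t_stimulus_onset")
  stopifnot(is.data.frame(trajectory), all(need %in% names(trajectory)))
  last <- max(trajectory$t_stimulus_onset)
  if (is.null(duration)) duration <- last + 30
  if (any(trajectory$t_trial_onset < 0) || last > duration) {
    abort("Event times must lie within [0, duration].")
  }
  grid <- seq(0, duration, by = dt)
  hrf <- do.call(hrf_double_gamma, c(list(t = seq(0, 32, by = dt)),
                                     hrf_args))
  make_reg <- function(onsets, weights) {
    w <- weights - mean(weights)
    train <- numeric(length(grid))
    idx <- pmin(length(grid), floor(onsets / dt) + 1L)
    for (i in seq_along(idx)) train[idx[i]] <- train[idx[i]] + w[i]
    convolve_truncate(train, hrf)
  }
  ec <- make_reg(trajectory$t_trial_onset, trajectory$c_bar_pre)
  pe <- make_reg(trajectory$t_stimulus_onset, trajectory$cpe)
  keep <- seq(1, length(grid), by = round(TR / dt))
  tibble(time = grid[keep], expected_confidence = ec[keep],
         cpe = pe[keep])
}
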