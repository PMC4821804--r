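#' Confidence-performance calibration curve
#'
#' Sorts trials by reported confidence and slides a window holding
#' `ceil(window_fraction * n)` trials across the sorted order in steps of
#' one trial, emitting the mean confidence (window centre) and the
#' proportion of correct responses per window.  A monotonically rising
#' curve indicates that confidence tracks accuracy.
#'
#' @param trials Data frame with `confidence` and logical `correct`.
#' @param window_fraction Window size as a fraction of all trials.
#' @return A `cl_calibration` tibble: `window`, `confidence` (window mean),
#'   `prop_correct`.
#' @export
confidence_performance_curve <- function(trials, window_fraction = 0.05) {
  stopifnot(is.data.frame(trials),
            all(c("confidence", "correct") %in% names(trials)))
  assert_scalar_num(window_fraction, "window_fraction", 0, 1,
                    strict_lower = TRUE)
  n <- nrow(trials)
  w <- ceiling(window_fraction * n)
  if (n < 1 / window_fraction) {
    abort("Too few trials for the requested window fraction.")
  }
  ord <- order(trials$confidence)
  conf <- trials$confidence[ord]
  corr <- as.numeric(trials$correct[ord])
  cs_conf <- c(0, cumsum(conf))
  cs_corr <- c(0, cumsum(corr))
  starts <- seq_len(n - w + 1L)
  out <- tibble(
    window = starts,
    confidence = (cs_conf[starts + w] - cs_conf[starts]) / w,
    prop_correct = (cs_corr[starts + w] - cs_corr[starts]) / w
  )
  class(out) <- c("cl_calibration", class(out))
  attr(out, "window_fraction") <- window_fraction
  out
}

#' Perceptual learning index
#'
#' Per-subject threshold improvement with the baseline regressed out:
#' improvement is `post - pre` (negative = lower threshold = better), the
#' improvements are regressed on the pre-test thresholds by ordinary
#' least squares (with intercept), and the learning index is the negated
#' residual, so that larger values mean more learning than expected from
#' the baseline alone.  The residuals — and hence the index — have mean
#' zero by construction.
#'
#' @param pre,post Paired per-subject thresholds (contrast percent),
#'   `n >= 3`.
#' @return A tibble: `subject`, `pre`, `post`, `improvement`,
#'   `learning_index`.
#' @export
perceptual_learning_index <- function(pre, post) {
  stopifnot(is.numeric(pre), is.numeric(post), length(pre) == length(post))
  if (length(pre) < 3) abort("Need at least 3 subjects.")
  if (sd(pre) == 0) abort("Zero variance in pre-test thresholds.")
  improvement <- post - pre
  fit <- lm(improvement ~ pre)
  tibble(subject = seq_along(pre), pre = pre, post = post,
         improvement = improvement,
         learning_index = -unname(residuals(fit)))
}

#' Linear slope of run-wise means
#'
#' Averages `value` within each run and fits an ordinary least-squares
#' line of the run means against the run index — the summary used for
#' contrast-threshold and read-out-weight trajectories across training.
#'
#' @param data Data frame with a run index column and a value column.
#' @param value Name of the value column (string).
#' @param run Name of the run index column (string).
#' @return A list with `slope`, `intercept`, and `run_means` (tibble:
#'   `run`, `mean`).
#' @export
slope_per_run <- function(data, value, run = "run") {
  stopifnot(is.data.frame(data), value %in% names(data),
            run %in% names(data))
  means <- data %>%
    group_by(run_idx = .data[[run]]) %>%
    summarise(mean = mean(.data[[value]]), .groups = "drop") %>%
    rename(run = "run_idx") %>%
    arrange(.data$run)
  if (nrow(means) < 2) abort("Need at least two runs.")
  fit <- lm(mean ~ run, data = means)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       run_means = means)
}

#' Group test of correlation coefficients via Fisher's z
#'
#' Transforms per-subject Pearson correlations with `z' = atanh(r)` and
#' runs a one-sample t-test of the z-transformed values against zero.
#'
#' @param r Per-subject correlation coefficients, all strictly inside
#'   (-1, 1), `n >= 2`.
#' @return A one-row tibble: `mean_z`, `mean_r` (back-transformed),
#'   `t`, `df`, `p_value`, `n`.
#' @export
fisher_z_group_test <- function(r) {
  stopifnot(is.numeric(r), length(r) >= 2)
  if (any(abs(r) >= 1)) abort("All |r| must be < 1 for the z-transform.")
  z <- atanh(r)
  n <- length(z)
  if (sd(z) == 0) {
    # degenerate case: identical correlations across subjects
    t_stat <- if (mean(z) == 0) 0 else sign(mean(z)) * Inf
    p <- if (mean(z) == 0) 1 else 0
  } else {
    tt <- t.test(z, mu = 0)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  tibble(mean_z = mean(z), mean_r = tanh(mean(z)),
         t = t_stat, df = n - 1, p_value = p, n = n)
}
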