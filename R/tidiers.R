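#' Tidy a subject-level model fit
#'
#' @param x A `cl_fit` from [fit_subject()].
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`.
#' @export
tidy.cl_fit <- function(x, ...) {
  if (is.null(x$params)) {
    return(tibble(term = character(), estimate = numeric()))
  }
  p <- x$params
  tibble(term = c("alpha_w", "alpha_c", "beta", "lambda", "sigma_c",
                  "w0_signal", "w0_noise"),
         estimate = c(p$alpha_w, p$alpha_c, p$beta, p$lambda, p$sigma_c,
                      p$w0_signal, p$w0_noise))
}

#' One-row summary of a subject-level fit
#'
#' @param x A `cl_fit`.
#' @param ... Unused.
#' @return A tibble: `neg_log_lik`, `n_trials`, `converged`,
#'   `n_restarts_used`.
#' @export
glance.cl_fit <- function(x, ...) {
  tibble(neg_log_lik = x$neg_log_lik, n_trials = x$n_trials,
         converged = x$converged, n_restarts_used = x$n_restarts_used)
}

#' Tidy a group-stage weight fit
#'
#' @param x A `cl_group_fit` from [fit_group_initial_weights()].
#' @param ... Unused.
#' @return A tibble with the two shared initial weights.
#' @export
tidy.cl_group_fit <- function(x, ...) {
  tibble(term = c("w0_signal", "w0_noise"),
         estimate = c(x$w0_signal, x$w0_noise))
}

#' One-row summary of a group-stage fit
#'
#' @param x A `cl_group_fit`.
#' @param ... Unused.
#' @return A tibble: `pooled_neg_log_lik`, `n_subjects`, `n_sweeps`.
#' @export
glance.cl_group_fit <- function(x, ...) {
  tibble(pooled_neg_log_lik = x$pooled_neg_log_lik,
         n_subjects = x$n_subjects, n_sweeps = x$n_sweeps)
}
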