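#' Joint negative log-likelihood of choices and confidence reports
#'
#' Runs the learning model in conditioned mode over the observed trials
#' and returns `-sum_t [log p(d_t) + log p(c_t)]`: the softmax likelihood
#' of each observed choice given the current decision value, plus the
#' censored-Gaussian likelihood of each confidence report around the
#' decisional certainty, with the weight trajectory driven by the observed
#' reports themselves.  Non-finite likelihoods return a large penalty so
#' the function is safe inside an optimiser.
#'
#' @param trials Data frame with normalised energies `E_ccw`, `E_cw`,
#'   observed `choice` (`"cw"`/`"ccw"`) and `confidence` in \[0, 1\].
#' @param params A [model_params()].
#' @param c_bar0 Initial expected confidence.
#' @param update_order See [run_session()].
#' @return A single number (negative log-likelihood).
#' @export
negative_log_likelihood <- function(trials, params, c_bar0 = 0.5,
                                    update_order = c("delta_first",
                                                     "cbar_first")) {
  update_order <- match.arg(update_order)
  stopifnot(is.data.frame(trials), inherits(params, "cl_model_params"),
            all(c("E_ccw", "E_cw", "choice", "confidence") %in%
                  names(trials)))
  if (any(trials$confidence < 0 | trials$confidence > 1)) {
    abort("Observed confidence must lie in [0, 1].")
  }
  if (!all(trials$choice %in% c("cw", "ccw"))) {
    abort("`choice` must be \"cw\" or \"ccw\".")
  }
  cl_nll_conditioned(
    trials$E_ccw, trials$E_cw,
    as.integer(trials$choice == "cw"), trials$confidence,
    params$alpha_w, params$alpha_c, params$beta, params$lambda,
    params$sigma_c, params$w0_signal, params$w0_noise,
    c_bar0, update_order == "cbar_first"
  )
}

# parameter transforms: unconstrained optimiser space <-> natural space
theta_to_params <- function(theta, w0) {
  model_params(alpha_w = exp(theta[1]),
               alpha_c = plogis(theta[2]),
               beta = exp(theta[3]),
               lambda = exp(theta[4]),
               sigma_c = exp(theta[5]),
               w0_signal = w0[1], w0_noise = w0[2])
}

params_to_theta <- function(params) {
  c(log(max(params$alpha_w, 1e-12)),
    qlogis(min(max(params$alpha_c, 1e-8), 1 - 1e-8)),
    log(max(params$beta, 1e-12)),
    log(max(params$lambda, 1e-12)),
    log(params$sigma_c))
}

# Latin-hypercube start points in transformed space
fit_start_box <- function() {
  rbind(log_alpha_w = log(c(1e-5, 0.3)),
        logit_alpha_c = c(-3, 3),
        log_beta = log(c(0.5, 80)),
        log_lambda = log(c(0.2, 20)),
        log_sigma_c = log(c(0.03, 0.8)))
}

#' Fit the five free model parameters to one subject's trials
#'
#' Stage-two maximum likelihood: with the initial weights fixed at `w0`,
#' the learning rates, inverse temperature, certainty scaling and report
#' noise (`alpha_w`, `alpha_c`, `beta`, `lambda`, `sigma_c`) are estimated
#' by minimising [negative_log_likelihood()] with a derivative-free
#' simplex in transformed space (log for the positive parameters, logit
#' for `alpha_c`), restarted from Latin-hypercube draws; the best restart
#' wins.
#'
#' @param trials One subject's trial table (see
#'   [negative_log_likelihood()]).
#' @param w0 Length-2 numeric: initial signal and noise weights, normally
#'   the group-stage estimates from [fit_group_initial_weights()].
#' @param n_restarts Number of Latin-hypercube restarts.
#' @param c_bar0 Initial expected confidence.
#' @param reltol,maxit Simplex convergence tolerance and iteration cap.
#' @param seed Integer seed for the restart draws.
#' @return A `cl_fit`: fitted [model_params()], `neg_log_lik`, `n_trials`,
#'   `converged`, `n_restarts_used`, `seed`, and the per-restart table.
#'   Works with [tidy()] and [glance()].
#' @export
fit_subject <- function(trials, w0 = c(0.5, 0.1), n_restarts = 10,
                        c_bar0 = 0.5, reltol = 1e-8, maxit = 2000,
                        seed = 1) {
  stopifnot(length(w0) == 2, is.numeric(w0))
  fn <- function(theta) {
    p <- try(theta_to_params(theta, w0), silent = TRUE)
    if (inherits(p, "try-error")) return(1e10)
    negative_log_likelihood(trials, p, c_bar0 = c_bar0)
  }
  box <- fit_start_box()
  starts <- with_seed(seed, lhs::randomLHS(n_restarts, nrow(box)))
  starts <- sweep(sweep(starts, 2, box[, 2] - box[, 1], `*`),
                  2, box[, 1], `+`)
  restarts <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    opt <- try(optim(starts[r, ], fn, method = "Nelder-Mead",
                     control = list(reltol = reltol, maxit = maxit)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    restarts[[r]] <- list(theta = opt$par, value = opt$value,
                          convergence = opt$convergence)
  }
  ok <- !vapply(restarts, is.null, TRUE)
  if (!any(ok)) {
    return(structure(list(params = NULL, neg_log_lik = Inf,
                          n_trials = nrow(trials), converged = FALSE,
                          n_restarts_used = n_restarts, seed = seed,
                          restarts = NULL, w0 = w0),
                     class = "cl_fit"))
  }
  vals <- vapply(restarts[ok], `[[`, 0, "value")
  best <- restarts[ok][[which.min(vals)]]
  structure(list(
    params = theta_to_params(best$theta, w0),
    neg_log_lik = best$value,
    n_trials = nrow(trials),
    converged = best$convergence == 0 && is.finite(best$value),
    n_restarts_used = n_restarts,
    seed = seed,
    restarts = tibble(restart = which(ok), value = vals),
    w0 = w0
  ), class = "cl_fit")
}

#' @export
print.cl_fit <- function(x, ...) {
  cat("<model fit> NLL = ", signif(x$neg_log_lik, 8), " over ",
      x$n_trials, " trials; converged = ", x$converged, "\n", sep = "")
  if (!is.null(x$params)) print(x$params)
  invisible(x)
}

#' Stage-one group estimation of the initial weights
#'
#' Estimates the initial signal and noise weights shared by all subjects
#' by maximising the likelihood pooled over subjects, with each subject's
#' five free parameters treated as nuisance and profiled out by
#' alternating optimisation: given the current weights, every subject is
#' refitted with [fit_subject()]; given the subject fits, the two weights
#' are optimised on the pooled likelihood; repeated for `n_sweeps`
#' sweeps.  Every subject's weight trajectory restarts at the shared
#' initial weights.
#'
#' @param trials_list A list of per-subject trial tables, or a single
#'   data frame with a `subject` column to split on.
#' @param w0_init Starting values for the shared weights.
#' @param n_sweeps Alternating-optimisation sweeps.
#' @param n_restarts Restarts per subject fit (kept modest; the sweep
#'   structure already re-polishes each subject).
#' @param c_bar0 Initial expected confidence.
#' @param seed Integer seed.
#' @return A `cl_group_fit`: `w0_signal`, `w0_noise`,
#'   `pooled_neg_log_lik`, and `per_subject_nuisance` (list of `cl_fit`).
#' @export
fit_group_initial_weights <- function(trials_list, w0_init = c(0.5, 0.1),
                                      n_sweeps = 2, n_restarts = 4,
                                      c_bar0 = 0.5, seed = 1) {
  if (is.data.frame(trials_list)) {
    if (!"subject" %in% names(trials_list)) {
      abort("A single data frame needs a `subject` column.")
    }
    trials_list <- split(trials_list, trials_list$subject)
  }
  stopifnot(length(trials_list) >= 1)
  n_sub <- length(trials_list)
  seeds <- derive_seeds(seed, n_sub + 1L)
  w0 <- w0_init
  fits <- NULL
  pooled <- function(w0, fits) {
    sum(vapply(seq_len(n_sub), function(i) {
      p <- fits[[i]]$params
      negative_log_likelihood(
        trials_list[[i]],
        model_params(p$alpha_w, p$alpha_c, p$beta, p$lambda, p$sigma_c,
                     w0[1], w0[2]),
        c_bar0 = c_bar0)
    }, 0))
  }
  refit_all <- function(w0) {
    lapply(seq_len(n_sub), function(i) {
      fit_subject(trials_list[[i]], w0 = w0, n_restarts = n_restarts,
                  c_bar0 = c_bar0, seed = seeds[i])
    })
  }
  for (s in seq_len(n_sweeps)) {
    fits <- refit_all(w0)
    opt <- optim(w0, pooled, fits = fits, method = "Nelder-Mead",
                 control = list(reltol = 1e-8, maxit = 500))
    w0 <- opt$par
  }
  # final pass so the stored nuisance fits consume the returned weights
  fits <- refit_all(w0)
  structure(list(
    w0_signal = w0[1], w0_noise = w0[2],
    pooled_neg_log_lik = pooled(w0, fits),
    per_subject_nuisance = fits,
    n_subjects = n_sub, n_sweeps = n_sweeps, seed = seed
  ), class = "cl_group_fit")
}

#' @export
print.cl_group_fit <- function(x, ...) {
  cat("<group fit> w0_signal = ", signif(x$w0_signal, 4),
      ", w0_noise = ", signif(x$w0_noise, 4), "; pooled NLL = ",
      signif(x$pooled_neg_log_lik, 8), " (", x$n_subjects,
      " subjects)\n", sep = "")
  invisible(x)
}
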