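#' Run the full desk-scale study analogue
#'
#' End-to-end orchestration: simulate a cohort of synthetic observers
#' through the complete experiment, estimate the shared initial weights
#' on the pooled training data (stage one), fit each subject's five free
#' parameters given those weights (stage two), and compute the summary
#' analyses — confidence-performance calibration, run-wise weight and
#' threshold slopes, the perceptual learning index, and the group
#' correspondence between model certainty and reported confidence
#' (Fisher-z).  All randomness fans out deterministically from
#' `master_seed`.
#'
#' @param cohort_size Number of synthetic observers.
#' @param spec An [observer_spec()] shared by the cohort.
#' @param design An [experiment_design()].
#' @param master_seed Integer master seed.
#' @param fit If `FALSE`, skip the (comparatively slow) model fitting.
#' @param n_restarts Restarts per subject fit.
#' @param out_dir Optional directory; when given, trial tables, fits and
#'   analyses are written as CSV/JSON together with a manifest of seeds
#'   and file hashes.
#' @return A `cl_pipeline` list: `experiments`, `trials` (pooled tibble
#'   with `subject`), `group_fit`, `subject_fits`, `analyses`, `seeds`.
#' @export
run_pipeline <- function(cohort_size = 8, spec = observer_spec(),
                         design = experiment_design(), master_seed = 1,
                         fit = TRUE, n_restarts = 4, out_dir = NULL) {
  stopifnot(cohort_size >= 1)
  seeds <- derive_seeds(master_seed, cohort_size + 1L)

  experiments <- lapply(seq_len(cohort_size), function(i) {
    simulate_experiment(spec, design, seed = seeds[i])
  })
  trials <- purrr::map_df(seq_len(cohort_size), function(i) {
    mutate(experiments[[i]]$trials, subject = i)
  })
  training <- filter(trials, .data$session == "training")

  # refit on the fitting-mode (session-max) energy scale, as for a real
  # participant whose raw energies have no absolute calibration
  fit_tables <- lapply(split(training, training$subject), function(d) {
    normalize_energies(select(d, -"E_ccw", -"E_cw"), mode = "session_max")
  })

  group_fit <- NULL
  subject_fits <- NULL
  if (fit) {
    group_fit <- fit_group_initial_weights(fit_tables,
                                           n_restarts = n_restarts,
                                           seed = seeds[cohort_size + 1L])
    w0 <- c(group_fit$w0_signal, group_fit$w0_noise)
    subject_fits <- lapply(seq_len(cohort_size), function(i) {
      fit_subject(fit_tables[[i]], w0 = w0, n_restarts = n_restarts,
                  seed = seeds[i])
    })
  }

  thresholds <- purrr::map_df(seq_len(cohort_size), function(i) {
    mutate(experiments[[i]]$thresholds, subject = i)
  })
  trained <- filter(thresholds, .data$axis == design$trained_axis)
  pli <- if (cohort_size >= 3) {
    perceptual_learning_index(
      pre = trained$threshold[trained$session == "pre_test"],
      post = trained$threshold[trained$session == "post_test"])
  }

  weight_slopes <- purrr::map_df(seq_len(cohort_size), function(i) {
    tr <- filter(experiments[[i]]$trials, .data$session == "training") %>%
      mutate(signal = (.data$w_ccw_ccw + .data$w_cw_cw) / 2,
             noise = (.data$w_ccw_cw + .data$w_cw_ccw) / 2)
    tibble(subject = i,
           signal_slope = slope_per_run(tr, "signal")$slope,
           noise_slope = slope_per_run(tr, "noise")$slope,
           contrast_slope = slope_per_run(
             filter(tr, .data$condition == "staircase"), "contrast")$slope)
  })

  confidence_fit <- if (fit) {
    r <- vapply(seq_len(cohort_size), function(i) {
      f <- subject_fits[[i]]
      if (is.null(f$params)) return(NA_real_)
      traj <- run_session(fit_tables[[i]], f$params, mode = "conditioned")
      cor(traj$certainty, fit_tables[[i]]$confidence)
    }, 0)
    r <- r[is.finite(r) & abs(r) < 1]
    if (length(r) >= 2) fisher_z_group_test(r)
  }

  calibration <- confidence_performance_curve(training)

  out <- structure(list(
    experiments = experiments, trials = trials, group_fit = group_fit,
    subject_fits = subject_fits,
    analyses = list(thresholds = thresholds, learning_index = pli,
                    weight_slopes = weight_slopes,
                    calibration = calibration,
                    confidence_fit = confidence_fit),
    seeds = list(master = master_seed, subjects = seeds[seq_len(cohort_size)],
                 group = seeds[cohort_size + 1L])
  ), class = "cl_pipeline")

  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

#' @export
print.cl_pipeline <- function(x, ...) {
  cat("<pipeline> ", length(x$experiments), " synthetic subjects, ",
      nrow(x$trials), " trials\n", sep = "")
  if (!is.null(x$group_fit)) print(x$group_fit)
  invisible(x)
}

write_pipeline <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(x$trials, "trials.csv")
  wr(x$analyses$thresholds, "thresholds.csv")
  wr(x$analyses$weight_slopes, "weight_slopes.csv")
  wr(as_tibble(x$analyses$calibration), "calibration.csv")
  if (!is.null(x$analyses$learning_index)) {
    wr(x$analyses$learning_index, "learning_index.csv")
  }
  if (!is.null(x$subject_fits)) {
    fits <- purrr::map_df(seq_along(x$subject_fits), function(i) {
      mutate(tidy(x$subject_fits[[i]]), subject = i)
    })
    wr(fits, "subject_fits.csv")
    jsonlite::write_json(
      list(w0_signal = x$group_fit$w0_signal,
           w0_noise = x$group_fit$w0_noise,
           pooled_neg_log_lik = x$group_fit$pooled_neg_log_lik),
      file.path(out_dir, "group_fit.json"), auto_unbox = TRUE, digits = NA)
    paths <- c(paths, file.path(out_dir, "group_fit.json"))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("conflearn")),
    seeds = x$seeds,
    files = lapply(setNames(paths, basename(paths)),
                   function(p) unname(tools::md5sum(p)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
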