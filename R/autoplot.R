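#' Plot a confidence-performance calibration curve
#'
#' @param object A `cl_calibration` from
#'   [confidence_performance_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cl_calibration <- function(object, ...) {
  ggplot(object, aes(x = .data$confidence, y = .data$prop_correct)) +
    geom_line(linewidth = 0.8, colour = "#2166ac") +
    geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    coord_cartesian(ylim = c(0.4, 1)) +
    labs(x = "Confidence (sliding-window mean)",
         y = "Proportion correct",
         title = "Confidence-performance calibration") +
    theme_minimal()
}

#' Plot a simulated BOLD time course
#'
#' @param object A `cl_bold` from [simulate_bold()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cl_bold <- function(object, ...) {
  ggplot(object, aes(x = .data$time, y = .data$bold)) +
    geom_vline(xintercept = c(-2, 0), linetype = "dotted",
               colour = "grey40") +
    geom_line(linewidth = 0.8, colour = "#b2182b") +
    labs(x = "Time from stimulus onset (s)", y = "Simulated BOLD (a.u.)",
         title = paste0("Scenario: ", attr(object, "scenario"))) +
    theme_minimal()
}

#' Plot the weight trajectories of a simulated experiment
#'
#' Run-wise means of the signal and noise weights across training.
#'
#' @param experiment A `cl_experiment` from [simulate_experiment()].
#' @return A ggplot.
#' @export
plot_weight_trajectories <- function(experiment) {
  stopifnot(inherits(experiment, "cl_experiment"))
  tr <- experiment$trials %>%
    filter(.data$session == "training") %>%
    mutate(signal = (.data$w_ccw_ccw + .data$w_cw_cw) / 2,
           noise = (.data$w_ccw_cw + .data$w_cw_ccw) / 2) %>%
    tidyr::pivot_longer(c("signal", "noise"), names_to = "weight_type",
                        values_to = "weight") %>%
    group_by(.data$run, .data$weight_type) %>%
    summarise(weight = mean(.data$weight), .groups = "drop")
  ggplot(tr, aes(x = .data$run, y = .data$weight,
                 colour = .data$weight_type)) +
    geom_line() + geom_point() +
    scale_x_continuous(breaks = unique(tr$run)) +
    labs(x = "Training run", y = "Mean weight", colour = NULL,
         title = "Read-out weights across training") +
    theme_minimal()
}

#' Plot a staircase contrast track
#'
#' @param log A staircase log tibble (from [run_staircase()] or
#'   [run_staircase_session()]) with `trial`, `contrast`, `reversal` and
#'   optionally `axis`.
#' @return A ggplot.
#' @export
plot_staircase <- function(log) {
  stopifnot(is.data.frame(log),
            all(c("trial", "contrast") %in% names(log)))
  p <- ggplot(log, aes(x = .data$trial, y = .data$contrast)) +
    geom_step(colour = "#2166ac") +
    geom_point(data = log[log$reversal, ], colour = "#b2182b",
               size = 1.6) +
    labs(x = "Trial", y = "Contrast (%)",
         title = "Adaptive staircase track") +
    theme_minimal()
  if ("axis" %in% names(log)) p <- p + facet_wrap(~axis)
  p
}

#' Plot a stimulus luminance image
#'
#' @param img A `cl_luminance_image`.
#' @return A ggplot (grayscale raster in degrees of visual angle).
#' @export
plot_stimulus <- function(img) {
  stopifnot(inherits(img, "cl_luminance_image"))
  dpp <- attr(img, "degrees_per_pixel")
  n <- nrow(img)
  co <- (seq_len(n) - (n + 1) / 2) * dpp
  df <- tidyr::expand_grid(y = co, x = co)
  df$lum <- as.vector(t(unclass(img)))  # row-major: y over rows
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$lum)) +
    geom_raster() +
    scale_fill_gradient(low = "black", high = "white") +
    scale_y_reverse() +
    coord_fixed() +
    labs(x = "x (deg)", y = "y (deg)", fill = "cd/m²") +
    theme_minimal()
}
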