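#' Plot posterior densities of a fit
#'
#' Per-chain kernel densities of every (or selected) parameter, one facet
#' per parameter. Coinciding chain densities are the visual convergence
#' check; a bimodal prevalence density is the expected signature of a
#' zero-inflated posterior.
#'
#' @param object A [fit_prevalence()] result.
#' @param parameters Optional subset of parameter names.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.prev_fit <- function(object, parameters = NULL, ...) {
  parameters <- parameters %||% object$parameters
  tabs <- purrr::map_dfr(parameters,
                         function(p) density_tables(object, p))
  tabs <- dplyr::filter(tabs, .data$segment == "full")
  ggplot2::ggplot(tabs, ggplot2::aes(.data$x, .data$density,
                                     colour = factor(.data$chain))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "Posterior density", colour = "Chain") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Traceplot
#'
#' @param fit A [fit_prevalence()] result.
#' @param parameters Optional subset of parameter names.
#' @return A ggplot object.
#' @export
plot_trace <- function(fit, parameters = NULL) {
  dd <- posterior_draws(fit, parameters)
  ggplot2::ggplot(dd, ggplot2::aes(.data$.iteration, .data$value,
                                   colour = factor(.data$.chain))) +
    ggplot2::geom_line(linewidth = 0.2, alpha = 0.8) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "Retained iteration", y = NULL, colour = "Chain") +
    ggplot2::theme_minimal()
}

#' Running-mean (ergodic mean) plot
#'
#' @param fit A [fit_prevalence()] result.
#' @param parameter Parameter name.
#' @return A ggplot object.
#' @export
plot_running_mean <- function(fit, parameter) {
  rm <- running_mean_series(fit, parameter)
  ggplot2::ggplot(rm, ggplot2::aes(.data$iteration, .data$running_mean,
                                   colour = factor(.data$chain))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Retained iteration", y = "Running mean",
                  colour = "Chain", title = parameter) +
    ggplot2::theme_minimal()
}

#' Autocorrelation plot
#'
#' @param fit A [fit_prevalence()] result.
#' @param parameter Parameter name.
#' @param max_lag Largest lag shown.
#' @return A ggplot object.
#' @export
plot_autocorrelation <- function(fit, parameter, max_lag = 40) {
  ac <- autocorrelation_series(fit, parameter, max_lag)
  ggplot2::ggplot(ac, ggplot2::aes(.data$lag, .data$autocorrelation)) +
    ggplot2::geom_col(width = 0.2) +
    ggplot2::labs(x = "Lag", y = "Autocorrelation", title = parameter) +
    ggplot2::theme_minimal()
}

#' Complete-versus-partial-chain density plot
#'
#' Overlays each chain's full-sample density with the densities of its two
#' halves; curves that do not coincide indicate within-chain drift or
#' non-convergence.
#'
#' @param fit A [fit_prevalence()] result.
#' @param parameter Parameter name.
#' @return A ggplot object.
#' @export
plot_partial_density <- function(fit, parameter) {
  tabs <- density_tables(fit, parameter)
  ggplot2::ggplot(tabs, ggplot2::aes(.data$x, .data$density,
                                     linetype = .data$segment)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~chain, labeller = ggplot2::label_both) +
    ggplot2::labs(x = parameter, y = "Density", linetype = "Segment") +
    ggplot2::theme_minimal()
}

#' Per-cluster posterior box plots
#'
#' One box per cluster from [cluster_boxplot_stats()] (Tukey whiskers),
#' the study-level display of a hierarchical fit.
#'
#' @param fit A `"true_multi"` [fit_prevalence()] result.
#' @return A ggplot object.
#' @export
plot_cluster_boxplots <- function(fit) {
  st <- cluster_boxplot_stats(fit)
  ggplot2::ggplot(st, ggplot2::aes(x = .data$cluster, ymin = .data$ymin,
                                   lower = .data$lower,
                                   middle = .data$middle,
                                   upper = .data$upper,
                                   ymax = .data$ymax)) +
    ggplot2::geom_boxplot(stat = "identity") +
    ggplot2::labs(x = NULL, y = "True prevalence") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
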