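#' Plot the sparsity pattern of a feedback gain
#'
#' Draws the nonzero entries of the gain matrix as points, the spy-plot view
#' in which sparse controllers reveal their structure: block-diagonal for
#' modular networks, cross-shaped for hub-centralized ones.
#'
#' @param object A `sparse_gain` from [sparse_gain_admm()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sparse_gain <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("gamma = %g: %d feedback channels, J = %.3f",
                      object$gamma, object$costs$card, object$costs$J),
      x = "sensor (column)", y = "actuator (row)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Mean total control cost per topology and channel price
#'
#' Line plot of the mean total cost against `gamma` (log scale), one line per
#' `tau`: the figure behind the regime orderings, showing which topology
#' class is cheapest to control as feedback channels get more expensive.
#'
#' @param table A results tibble from [run_sweep()].
#' @return A ggplot object.
#' @export
plot_regime_costs <- function(table) {
  d <- table |>
    dplyr::filter(!is.na(.data$total)) |>
    dplyr::group_by(.data$tau, .data$gamma) |>
    dplyr::summarise(mean_total = mean(.data$total), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gamma, y = .data$mean_total,
                                  colour = factor(.data$tau))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "feedback channel price gamma",
                  y = "mean total cost J + gamma card(F)",
                  colour = "tau") +
    ggplot2::theme_minimal()
}

#' Metric-versus-cost scatter across an ensemble
#'
#' Scatter of a topology metric (degree spread or modularity) against a cost
#' column, colored by `gamma`.
#'
#' @param table A results tibble from [run_sweep()].
#' @param metric One of `"degree_std"`, `"Q"`, `"Q_norm"`.
#' @param response One of `"J"`, `"card"`, `"total"`, `"n_driver"`.
#' @return A ggplot object.
#' @export
plot_metric_cost <- function(table, metric = "degree_std", response = "J") {
  ggplot2::ggplot(table,
                  ggplot2::aes(x = .data[[metric]], y = .data[[response]],
                               colour = factor(.data$gamma))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(colour = "gamma") +
    ggplot2::theme_minimal()
}
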