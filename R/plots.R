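# ggplot2 displays for the main result types.

#' Variable-importance bar chart for a penalized fit
#'
#' Horizontal bars of relative importance (absolute standardized
#' coefficient, max scaled to 100), colored by effect direction.
#'
#' @param object A `polyenv_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.polyenv_fit <- function(object, ...) {
  imp <- variable_importance(object)
  if (nrow(imp) == 0L) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", 0, 0, label = "no active predictors") +
             ggplot2::theme_void())
  }
  ggplot2::ggplot(imp, ggplot2::aes(
    x = .data$importance,
    y = stats::reorder(.data$term, .data$importance),
    fill = .data$sign)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "relative importance", y = NULL, fill = "direction",
                  title = sprintf("%s model: selected predictors", object$model)) +
    ggplot2::theme_minimal()
}

#' Bootstrap R-squared distributions across models
#'
#' Density ridgeline-style display of the per-model bootstrap hold-out
#' R-squared distributions with their 95% percentile intervals.
#'
#' @param object A `polyenv_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.polyenv_comparison <- function(object, ...) {
  draws <- tibble::as_tibble(object$r2_draws) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "model",
                        values_to = "r2") |>
    dplyr::filter(!is.na(.data$r2))
  ggplot2::ggplot(draws, ggplot2::aes(x = .data$r2, fill = .data$model)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::geom_vline(data = object$r2,
                        ggplot2::aes(xintercept = .data$r2, color = .data$model),
                        linetype = 2, show.legend = FALSE) +
    ggplot2::labs(x = expression(hold-out ~ R^2), y = "bootstrap density") +
    ggplot2::theme_minimal()
}

#' Mediation path diagram values
#'
#' Dot-and-interval display of the mediation path estimates with their
#' bootstrap intervals.
#'
#' @param object A `polyenv_mediation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.polyenv_mediation <- function(object, ...) {
  ggplot2::ggplot(object$estimates,
                  ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lower,
                                          xmax = .data$upper)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(title = sprintf("mediation paths (%s)", object$orientation),
                  x = "estimate (bootstrap 95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Selected interaction map
#'
#' Tile map of the selected pairs from a hierarchical interaction fit,
#' shaded by group weight and labelled by class (GxE / GxG / ExE).
#'
#' @param object A `polyenv_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.polyenv_selection <- function(object, ...) {
  if (nrow(object$pairs) == 0L) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", 0, 0, label = "no interactions selected") +
             ggplot2::theme_void())
  }
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$var1, y = .data$var2,
                               fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$class), size = 3) +
    ggplot2::labs(x = NULL, y = NULL, fill = "group norm") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
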