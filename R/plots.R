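#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot melt curves with estimated melting temperatures
#'
#' @param curves Long melt-curve tibble (`condition_id`, `temperature_C`,
#'   `fluorescence`).
#' @param tm_results Optional [estimate_tm()] output; detected midpoints are
#'   drawn as dashed verticals.
#' @return A ggplot object.
#' @export
plot_melt_curves <- function(curves, tm_results = NULL) {
  p <- ggplot2::ggplot(curves, ggplot2::aes(.data$temperature_C,
                                            .data$fluorescence,
                                            colour = .data$condition_id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Temperature (°C)", y = "Fluorescence (AU)",
                  colour = "Condition") +
    ggplot2::theme_minimal()
  if (!is.null(tm_results)) {
    tms <- tm_results[tm_results$transition_detected, ]
    p <- p + ggplot2::geom_vline(
      data = tms, ggplot2::aes(xintercept = .data$tm_C,
                               colour = .data$condition_id),
      linetype = "dashed", show.legend = FALSE
    )
  }
  p
}

#' Plot a Michaelis-Menten fit over its rate data
#'
#' @param object An `mm_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mm_fit <- function(object, ...) {
  S <- object$data$substrate_uM
  grid <- tibble::tibble(substrate_uM = seq(min(S), max(S), length.out = 200))
  grid$rate_uM_per_s <- object$vmax_uM_per_s * grid$substrate_uM /
    (object$km_uM + grid$substrate_uM)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$substrate_uM, .data$rate_uM_per_s)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(
      x = "Substrate (µM)", y = "Rate (µM/s)",
      title = sprintf("Km = %.3g µM, Vmax = %.3g µM/s",
                      object$km_uM, object$vmax_uM_per_s)
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of a product profile
#'
#' @param object A `product_profile` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.product_profile <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$compound,
                                                  .data$percent),
                                   .data$percent)) +
    ggplot2::geom_col(fill = "darkseagreen") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Percent of total terpenes",
                  title = paste(object$sample_id, "+", object$substrate)) +
    ggplot2::theme_minimal()
}

#' Bar charts of corpus component frequencies
#'
#' @param object A `frequency_report` object.
#' @param ... Unused.
#' @return A ggplot object faceted by category.
#' @export
autoplot.frequency_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$name, .data$percent),
                                   .data$percent)) +
    ggplot2::geom_col(fill = "slateblue") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~category, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Percent of reporting conditions") +
    ggplot2::theme_minimal()
}
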