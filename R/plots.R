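# ggplot2 views of the result objects.  All plot functions return ggplot
# objects for further styling.

#' @describeIn spectrum_report Eigenvalues in the complex plane with the
#'   predicted bulk circle and mean-input outlier.
#' @param object A `spectrum_report`.
#' @export
autoplot.spectrum_report <- function(object, ...) {
  ev <- tidy(object)
  th <- seq(0, 2 * pi, length.out = 256)
  circle <- tibble(
    re = object$predicted_bulk_radius * cos(th),
    im = object$predicted_bulk_radius * sin(th)
  )
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$re, y = .data$im)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_path(data = circle, colour = "red") +
    ggplot2::annotate("point",
      x = object$predicted_mean_outlier, y = 0,
      colour = "red", shape = 4, size = 3
    ) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "Re λ", y = "Im λ",
      title = "Connectivity spectrum",
      subtitle = sprintf(
        "predicted bulk radius %.3g, mean-input outlier %.3g",
        object$predicted_bulk_radius, object$predicted_mean_outlier
      )
    )
}

#' @describeIn distance_correlation_analytic Per-order and total analytic
#'   correlation versus signed ring offset.
#' @param object A `ring_profile_set`.
#' @export
autoplot.ring_profile_set <- function(object, ...) {
  df <- tidy(object)
  df <- df[!(df$component == "total" & df$offset == 0), ] # rate delta dominates
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$offset, y = .data$value,
    colour = .data$component
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "ring offset d", y = "correlation c(d)",
      title = "Distance-dependent correlations (analytic)"
    )
}

#' @describeIn simulate_hawkes Spike raster.
#' @param object A `spike_trains` tibble.
#' @param ... Unused.
#' @export
autoplot.spike_trains <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$time, y = .data$neuron)
  ) +
    ggplot2::geom_point(shape = ".", alpha = 0.6) +
    ggplot2::labs(x = "time (s)", y = "neuron", title = "Spike raster")
}

#' Bar chart of per-order motif contributions
#'
#' Stacked chain / common-input contributions to the average correlation per
#' total path length, as produced by [average_contributions()] or the
#' closed-form tibble of [avg_correlation_closed_form()].
#'
#' @param contributions Tibble with columns `order`, `chain`, `common_input`.
#' @return A ggplot object.
#' @export
plot_motif_contributions <- function(contributions) {
  df <- contributions |>
    dplyr::select("order", "chain", "common_input") |>
    tidyr::pivot_longer(c("chain", "common_input"),
      names_to = "motif_class", values_to = "contribution"
    )
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$order), y = .data$contribution, fill = .data$motif_class
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(
      x = "motif order (total path length)", y = "contribution to mean correlation",
      fill = NULL, title = "Motif contributions to the average correlation"
    )
}
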