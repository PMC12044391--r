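#' Plot a response map as paired heatmaps
#'
#' Tile heatmaps of mean CIL and mean alignment over the contact-angle by
#' neighbour-speed grid, one facet per metric.
#'
#' @param object A [response_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.response_map <- function(object, ...) {
  df <- object$cells |>
    tidyr::pivot_longer(c("mean_cil", "mean_alignment"),
                        names_to = "metric", values_to = "value") |>
    dplyr::mutate(
      metric = dplyr::recode(.data$metric, mean_cil = "CIL",
                             mean_alignment = "alignment"),
      speed_class = factor(.data$speed_class,
                           levels = object$speed_classes))
  ggplot2::ggplot(df, ggplot2::aes(
    x = (.data$phi_lo + .data$phi_hi) / 2,
    y = .data$speed_class, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~metric, ncol = 1) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1),
                                  na.value = "grey85") +
    ggplot2::scale_x_continuous(
      breaks = c(0, pi / 2, pi),
      labels = c("0 (front)", expression(pi / 2), expression(pi ~ "(rear)"))) +
    ggplot2::labs(x = expression("contact angle" ~ phi),
                  y = "neighbour speed", fill = "mean") +
    ggplot2::theme_minimal()
}

#' Plot a directionality time series
#'
#' @param series Output of [directionality()].
#' @param schedule Optional [field_schedule()] to shade field-on periods.
#' @return A ggplot object.
#' @export
plot_directionality <- function(series, schedule = NULL) {
  p <- ggplot2::ggplot(series, ggplot2::aes(x = .data$t_min / 60))
  if (!is.null(schedule) && nrow(schedule)) {
    p <- p + ggplot2::geom_rect(
      data = as.data.frame(schedule),
      ggplot2::aes(xmin = .data$t_on / 60, xmax = .data$t_off / 60,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "gold", alpha = 0.15)
  }
  p +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line(ggplot2::aes(y = .data$phi), na.rm = TRUE) +
    ggplot2::labs(x = "time (h)", y = expression(Phi)) +
    ggplot2::coord_cartesian(ylim = c(-1, 1)) +
    ggplot2::theme_minimal()
}

#' Plot the pre/post reversal perpendicular-velocity distributions
#'
#' @param object A [reversal_comparison()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reversal_comparison <- function(object, ...) {
  df <- dplyr::mutate(object$samples,
                      period = factor(.data$period, c("pre", "post")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$period, y = .data$vy_umh)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_boxplot(width = 0.12, outlier.shape = NA) +
    ggplot2::labs(
      x = NULL, y = expression(v[y] ~ "(" * mu * "m/h)"),
      subtitle = sprintf("Mann-Whitney two-sided p = %.3g", object$p_value)) +
    ggplot2::theme_minimal()
}
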