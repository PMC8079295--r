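#' Plot a broken-stick threshold fit
#'
#' Residence in the hypoxic compartment against DO, with the two fixed-effect
#' regression lines (each drawn over its own segment's DO range) and the
#' threshold marked at their intersection.
#'
#' @param object A `broken_stick_fit`.
#' @param data The residence dataset the fit was computed from; required to
#'   show the points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.broken_stick_fit <- function(object, data = NULL, ...) {
  pre <- object$pre_fit$coefficients$estimate
  post <- object$post_fit$coefficients$estimate
  thr <- object$threshold
  p <- ggplot2::ggplot()
  if (!is.null(data)) {
    p <- p + ggplot2::geom_jitter(
      data = data, ggplot2::aes(x = .data$do, y = .data$residence),
      width = 1, height = 0, alpha = 0.4, colour = "grey40")
  }
  rng <- if (is.null(data)) c(thr - 20, thr + 60) else range(data$do)
  seg <- function(b, from, to) {
    tibble::tibble(x = c(from, to), y = b[1] + b[2] * c(from, to))
  }
  p +
    ggplot2::geom_line(data = seg(pre, thr, rng[2]),
                       ggplot2::aes(.data$x, .data$y), linetype = "dashed") +
    ggplot2::geom_line(data = seg(post, rng[1], thr),
                       ggplot2::aes(.data$x, .data$y), linetype = "dashed") +
    ggplot2::annotate("point", x = thr, y = pre[1] + pre[2] * thr,
                      shape = 18, size = 4) +
    ggplot2::labs(x = "DO (% air saturation)",
                  y = "Residence in hypoxic compartment (%)",
                  title = sprintf("Hypoxia-avoidance threshold: %.1f %% air saturation", thr)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot behavioural metrics per interval
#'
#' Faceted interval medians (across fish) of the behavioural metrics, in
#' trial order.
#'
#' @param summaries Output of [bin_intervals()] for one or more fish.
#' @return A ggplot object.
#' @export
plot_interval_metrics <- function(summaries) {
  long <- summaries |>
    tidyr::pivot_longer(c("residence_hypoxic", "shelter_time", "side_changes",
                          "distance_m", "velocity_median_bls"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$interval_id, .data$metric) |>
    dplyr::summarise(median = stats::median(.data$value),
                     q1 = stats::quantile(.data$value, 0.25),
                     q3 = stats::quantile(.data$value, 0.75), .groups = "drop")
  long$interval_id <- factor(long$interval_id,
                             levels = unique(summaries$interval_id))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$interval_id, y = .data$median)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q1, ymax = .data$q3),
                             size = 0.3) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Interval", y = "Median (IQR) across fish") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot an EOD frequency track
#'
#' @param object A `frequency_track`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.frequency_track <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t_s / 60, y = .data$freq_hz)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Trial time (min)", y = "EOD frequency (Hz)",
                  title = attr(object, "fish_id")) +
    ggplot2::theme_minimal()
}
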