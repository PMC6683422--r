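#' Plot cost-effectiveness acceptability curves
#'
#' One curve per arm: the probability of being cost-effective (maximum
#' net monetary benefit among arms) as a function of willingness-to-pay.
#'
#' @param ceac_table A [ceac()] result.
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_table) {
  ggplot2::ggplot(ceac_table,
                  ggplot2::aes(x = .data$wtp, y = .data$probability,
                               colour = .data$arm)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::scale_x_continuous(labels = function(x) {
      paste0("$", format(x, big.mark = ",", scientific = FALSE))
    }) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Willingness-to-pay per QALY",
                  y = "Probability cost-effective", colour = "Arm") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.depcea_ceac <- function(object, ...) plot_ceac(object)

#' Plot the incremental cost-effectiveness plane
#'
#' Scatter of the Monte Carlo (QALY difference, cost difference) pairs
#' with the willingness-to-pay threshold line through the origin; points
#' below the line favour the first arm of the comparison.
#'
#' @param points A [scatter_points()] result.
#' @param wtp Willingness-to-pay line to draw (default $50,000/QALY).
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(points, wtp = 50000) {
  arms <- attr(points, "arms") %||% c("A", "B")
  frac <- fraction_below(points, wtp)
  ggplot2::ggplot(points, ggplot2::aes(x = .data$delta_qaly,
                                       y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.6) +
    ggplot2::geom_abline(slope = wtp, intercept = 0,
                         linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::labs(
      x = sprintf("Incremental QALYs (%s vs %s)", arms[1], arms[2]),
      y = "Incremental cost (2017 CAD)",
      title = sprintf("%.0f%% of points below the $%s/QALY line",
                      100 * frac, format(wtp, big.mark = ","))) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.depcea_scatter <- function(object, ...) plot_ce_plane(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
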