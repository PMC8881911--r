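#' Plot a bias estimate
#'
#' Per-taxon detection efficiency relative to the geometric-mean taxon, on a
#' log axis, with 95% (thin) and 50% (thick) bootstrap intervals when
#' available.
#'
#' @param x A `bias_estimate`.
#' @return A ggplot object.
#' @export
plot_bias <- function(x) {
  stopifnot(inherits(x, "bias_estimate"))
  tab <- tibble::as_tibble(x)
  tab$taxon <- factor(tab$taxon, levels = tab$taxon[order(tab$efficiency)])
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$efficiency,
                                         y = .data$taxon)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "detection efficiency (relative to mean taxon)",
                  y = NULL, title = x$group) +
    ggplot2::theme_minimal()
  if (!all(is.na(tab$ci_lo))) {
    p <- p +
      ggplot2::geom_errorbarh(
        ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi),
        height = 0, linewidth = 0.4) +
      ggplot2::geom_errorbarh(
        ggplot2::aes(xmin = .data$ci50_lo, xmax = .data$ci50_hi),
        height = 0, linewidth = 1.1)
  }
  p
}

#' Plot per-taxon abundance trajectories through the workflow
#'
#' Relative abundance of each taxon (starting at one) after each protocol
#' step, centered to the geometric-mean taxon.
#'
#' @param trajectory Tibble from [bias_trajectory()].
#' @return A ggplot object.
#' @export
plot_trajectory <- function(trajectory) {
  long <- tidyr::pivot_longer(trajectory, -"taxon",
                              names_to = "step", values_to = "abundance")
  long$step <- factor(long$step,
                      levels = c("start", "extraction", "pcr", "sequencing"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$abundance,
                                     group = .data$taxon,
                                     colour = .data$taxon)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "relative abundance (start = 1)") +
    ggplot2::theme_minimal()
}
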