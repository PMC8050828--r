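#' Box-scatter panel of fractional intensities per population
#'
#' One box per population with the per-vesicle f values overlaid as jittered
#' points, and a dotted line at f = 0.5 (no partitioning) — the standard
#' presentation of partitioning data.
#'
#' @param records data.frame of partition records.
#' @return a ggplot object.
#' @export
plot_box_scatter <- function(records) {
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$population_label, y = .data$f_p_Lo)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.6, size = 1.4) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = expression(f[p * ",Lo"])) +
    ggplot2::theme_classic()
}

#' Measured vs additively predicted free energies
#'
#' Scatter of measured population-mean dG against the additive multi-anchor
#' prediction, with the identity line; points on the line indicate additive
#' behaviour.
#'
#' @param predictions data.frame from [run_analyze()] (`dG_pred`,
#'   `dG_measured`, `design`).
#' @return a ggplot object.
#' @export
plot_measured_vs_predicted <- function(predictions) {
  ggplot2::ggplot(predictions,
                  ggplot2::aes(x = .data$dG_pred, y = .data$dG_measured,
                               label = .data$design)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(x = expression(Delta * G[pred] ~ "(" * k[B] * T * ")"),
                  y = expression(Delta * G[measured] ~ "(" * k[B] * T * ")")) +
    ggplot2::theme_classic()
}

#' Save a figure to a PNG file
#'
#' @param p a ggplot object.
#' @param path output path.
#' @param width,height,dpi device geometry.
#' @return `path`, invisibly.
#' @export
save_figure <- function(p, path, width = 5, height = 4, dpi = 150) {
  grDevices::png(path, width = width * dpi, height = height * dpi, res = dpi)
  on.exit(grDevices::dev.off())
  print(p)
  invisible(path)
}
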