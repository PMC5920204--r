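#' @include evaluation.R
#' @importFrom ggplot2 .data
NULL

#' Normalized-velocity sweep plot
#'
#' Plots mean normalized velocity (measured / actual) against the
#' ground-truth axial velocity on a log scale, one curve per estimator,
#' with standard-error bars — the standard way to visualize accuracy and
#' precision of the estimators over a wide velocity range.
#'
#' @param sweep Sweep data.frame from [runSweep()] (may contain several
#'   estimators).
#' @param ylim Normalized-velocity axis limits.
#' @return A ggplot object.
#' @export
plotSweep <- function(sweep, ylim = c(0, 2)) {
  stopifnot(is.data.frame(sweep))
  sweep <- sweep[!is.na(sweep$mean_normalized_velocity), , drop = FALSE]
  ggplot2::ggplot(
    sweep,
    ggplot2::aes(x = .data$velocity_mps * 1e3,
                 y = .data$mean_normalized_velocity,
                 colour = .data$estimator, group = .data$estimator)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_normalized_velocity -
                     .data$standard_error,
                   ymax = .data$mean_normalized_velocity +
                     .data$standard_error),
      width = 0.05) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::coord_cartesian(ylim = ylim) +
    ggplot2::labs(x = "axial velocity (mm/s, log scale)",
                  y = "normalized velocity (measured / actual)",
                  colour = "estimator") +
    ggplot2::theme_minimal()
}
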