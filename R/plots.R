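# ggplot2 helpers for the package's result types.

#' Plot simulated gain curves
#'
#' Mean realized gain against the total selection proportion, one line per
#' strategy, with 95% confidence ribbons; facetted by scenario when several
#' are present.
#'
#' @param gains A `gain_estimate` tibble (e.g. the `gains_simulated` table
#'   of a [full_experiment()]). Two-stage rows are reduced to their per-TSP
#'   optimum.
#' @param ci Draw confidence ribbons.
#' @return A ggplot object.
#' @export
plot_gain_curves <- function(gains, ci = TRUE) {
  two <- filter(gains, .data$strategy == "two_stage")
  if (nrow(two)) {
    two <- ungroup(slice_max(
      group_by(two, .data$scenario, .data$population, .data$dominance, .data$tsp),
      .data$mean_gain, n = 1, with_ties = FALSE
    ))
    gains <- bind_rows(filter(gains, .data$strategy != "two_stage"), two)
  }
  p <- ggplot2::ggplot(gains, ggplot2::aes(.data$tsp, .data$mean_gain,
                                           colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "total selection proportion (TSP)",
                  y = "genetic gain (trait units)", colour = "strategy") +
    ggplot2::theme_minimal()
  if (ci) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high,
                   fill = .data$strategy),
      alpha = 0.2, colour = NA
    ) + ggplot2::labs(fill = "strategy")
  }
  if (length(unique(gains$scenario)) > 1L) {
    p <- p + ggplot2::facet_wrap(~scenario, labeller = ggplot2::label_both)
  }
  p
}

#' Plot a two-stage SP_M scan
#'
#' Mean realized two-stage gain against the first-stage proportion at a
#' fixed total selection proportion.
#'
#' @param scan A `gain_estimate` tibble from [two_stage_scan()].
#' @return A ggplot object.
#' @export
plot_two_stage_scan <- function(scan) {
  ggplot2::ggplot(scan, ggplot2::aes(.data$spm, .data$mean_gain)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high), size = 0.3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "first-stage proportion (SP_M)",
                  y = "genetic gain (trait units)") +
    ggplot2::theme_minimal()
}

#' @method autoplot seedling_population
#' @export
autoplot.seedling_population <- function(object, binwidth = 2, ...) {
  ggplot2::ggplot(as_tibble(unclass_tbl(object)),
                  ggplot2::aes(.data$z, fill = .data$genotype)) +
    ggplot2::geom_histogram(binwidth = binwidth, position = "identity",
                            alpha = 0.6) +
    ggplot2::labs(x = "phenotypic value", y = "seedlings") +
    ggplot2::theme_minimal()
}

#' @method autoplot marker_table
#' @export
autoplot.marker_table <- function(object, ...) {
  ggplot2::ggplot(as_tibble(unclass_tbl(object)),
                  ggplot2::aes(.data$value, .data$freq)) +
    ggplot2::geom_col(width = diff(range(object$value)) / 40 + 1e-9) +
    ggplot2::labs(x = "class mean genotypic value (adjusted scale)",
                  y = "frequency") +
    ggplot2::theme_minimal()
}

#' @method autoplot seedgain_experiment
#' @export
autoplot.seedgain_experiment <- function(object, ...) {
  plot_gain_curves(object$gains_simulated, ...)
}

#' @method autoplot gain_estimate
#' @export
autoplot.gain_estimate <- function(object, ...) {
  if (all(object$strategy == "two_stage") &&
      length(unique(object$tsp)) == 1L && !anyNA(object$spm)) {
    plot_two_stage_scan(object)
  } else {
    plot_gain_curves(object, ...)
  }
}
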