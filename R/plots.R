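#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a set of estimated curves
#'
#' Lines per unit with pointwise confidence ribbons (when standard errors are
#' present), coloured by population and faceted by population for
#' genotype- and plant-level sets.
#'
#' @param object a `curve_set` from [evaluate_curves()] or
#'   [evaluate_derivatives()].
#' @param ... unused.
#' @export
autoplot.curve_set <- function(object, ...) {
  p <- ggplot2::ggplot(object,
         ggplot2::aes(x = .data$time, y = .data$estimate,
                      group = .data$unit, colour = .data$population))
  if (!all(is.na(object$se))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper,
                   fill = .data$population),
      alpha = 0.15, colour = NA)
  }
  p <- p + ggplot2::geom_line()
  if (length(unique(object$population)) > 1 &&
      object$level[1] != "population") {
    p <- p + ggplot2::facet_wrap(~population)
  }
  p + ggplot2::labs(x = "time", y = unique(object$kind)[1]) +
    ggplot2::theme_minimal()
}

#' Plot extracted genotype traits
#'
#' Scatter of the deviation area against the curve maximum, coloured by
#' population: genotypes above zero on the y axis outperform their
#' population average over the measured interval.
#'
#' @param object a `trait_table` from [build_trait_table()].
#' @param ... unused.
#' @export
autoplot.trait_table <- function(object, ...) {
  ggplot2::ggplot(object,
    ggplot2::aes(x = .data$maxTrait_value, y = .data$auc,
                 colour = .data$population)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "curve maximum (maxTrait)",
                  y = "area under genotype deviation") +
    ggplot2::theme_minimal()
}

#' Raw versus spatially corrected series
#'
#' Time profiles of the raw and corrected phenotype for a set of plants,
#' faceted by genotype — the corrected replicates of a genotype should be
#' visibly tighter than the raw ones when spatial trends are present.
#'
#' @param series a `corrected_series` from [run_stage1()].
#' @param genotypes genotypes to display (default: first 4).
#' @export
plot_correction <- function(series, genotypes = NULL) {
  if (is.null(genotypes)) {
    genotypes <- utils::head(unique(series$genotype), 4)
  }
  df <- series[series$genotype %in% genotypes & !series$missing, ]
  long <- tidyr::pivot_longer(df, c("value", "corrected"),
                              names_to = "series", values_to = "y")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$y,
                                     group = interaction(.data$plant, .data$series),
                                     colour = .data$series)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_wrap(~genotype) +
    ggplot2::labs(y = "phenotype", colour = NULL) +
    ggplot2::theme_minimal()
}
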