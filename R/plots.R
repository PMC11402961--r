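# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a hydration histogram
#'
#' The water-solute distance probability density P(d) against distance.
#'
#' @param object A [hydration_histogram()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hydration_histogram <- function(object, ...) {
  df <- tibble::tibble(distance_nm = object$bin_centers,
                       density = object$density)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance_nm, y = .data$density)) +
    ggplot2::geom_col(width = diff(object$bin_edges)[1], fill = "steelblue") +
    ggplot2::labs(x = "water-solute distance d (nm)",
                  y = expression(P(d) ~ (nm^-1))) +
    ggplot2::theme_minimal()
}

#' Predicted versus observed %MGS for a leave-one-out run
#'
#' @param object An `iri_loo` (regression) tibble.
#' @param ... Unused.
#' @return A ggplot with the identity line and the PCC/MSE annotation.
#' @export
autoplot.iri_loo <- function(object, ...) {
  if (identical(attr(object, "task"), "classification")) {
    df <- tibble::as_tibble(unclass(object))
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$prediction,
                                       colour = .data$observed_label)) +
        ggplot2::geom_point() +
        ggplot2::labs(x = "observed %MGS", y = "P(active)", colour = NULL) +
        ggplot2::theme_minimal()
    )
  }
  met <- regression_metrics(object$observed, object$prediction)
  ggplot2::ggplot(tibble::as_tibble(unclass(object)),
                  ggplot2::aes(x = .data$observed, y = .data$prediction)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = "experimental %MGS", y = "predicted %MGS",
                  subtitle = sprintf("PCC = %.2f, MSE = %.0f", met$pcc, met$mse)) +
    ggplot2::theme_minimal()
}

#' Activity-threshold sweep plot
#'
#' Fraction of compounds labelled active as the %MGS activity threshold
#' varies -- the diagnostic for how arbitrary the class boundary is.
#'
#' @param compounds Compound tibble with `mgs_percent`.
#' @param thresholds Thresholds (%MGS) to sweep.
#' @return A ggplot.
#' @export
plot_threshold_sweep <- function(compounds, thresholds = seq(50, 90, by = 10)) {
  df <- tibble::tibble(
    threshold = thresholds,
    active_fraction = vapply(thresholds, function(th) {
      mean(label_activity(compounds$mgs_percent, th) == "active")
    }, numeric(1))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$active_fraction)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = "activity threshold (%MGS)", y = "fraction labelled active") +
    ggplot2::theme_minimal()
}

#' Hydration-correlation heatmap
#'
#' Tile map of the Pearson correlations from
#' [hydration_correlation_report()]: one row per size metric (plus the raw
#' hydration numbers), one column per cutoff specification.
#'
#' @param report A [hydration_correlation_report()] tibble.
#' @return A ggplot.
#' @export
plot_hydration_heatmap <- function(report) {
  df <- dplyr::mutate(report,
                      row = ifelse(is.na(.data$metric), "number",
                                   paste0("index/", .data$metric)),
                      cutoff_spec = factor(.data$cutoff_spec,
                                           levels = unique(.data$cutoff_spec)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cutoff_spec, y = .data$row,
                                   fill = .data$pcc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  limits = c(-1, 1), na.value = "grey80") +
    ggplot2::labs(x = "hydration-number cutoff", y = NULL, fill = "PCC") +
    ggplot2::theme_minimal()
}

#' Screening outcome plot
#'
#' Predicted %MGS with uncertainty for a screened library, highlighting the
#' prediction set.
#'
#' @param object An [screen_library()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.iri_screen <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  df$rank <- seq_len(nrow(df))
  df$status <- dplyr::case_when(df$uncertain ~ "filtered (SD)",
                                !is.na(df$selected) ~ df$selected,
                                TRUE ~ "unselected")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$ensemble_mean,
                                   colour = .data$status)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ensemble_mean - .data$ensemble_sd,
                                          ymax = .data$ensemble_mean + .data$ensemble_sd),
                             fatten = 1.5) +
    ggplot2::labs(x = "rank (predicted most active first)",
                  y = "predicted %MGS", colour = NULL) +
    ggplot2::theme_minimal()
}
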