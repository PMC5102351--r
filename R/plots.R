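#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_segment
#'   labs facet_wrap scale_linetype_manual theme_minimal position_dodge
NULL

#' @export
ggplot2::autoplot

#' Plot exceedance response curves
#'
#' One curve per temperature, solid inside and dashed outside the
#' historical rainbow-trout range, probability against distance to the
#' nearest propagule source.
#'
#' @param object a [response_curves()] tibble.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot response_curves
#' @export
autoplot.response_curves <- function(object, ...) {
  ggplot(object, aes(x = .data$ds_m / 1000, y = .data$probability,
                     colour = factor(.data$t_aug_c),
                     linetype = factor(.data$rt_range,
                                       levels = c(1, 0),
                                       labels = c("inside", "outside")))) +
    geom_line() +
    labs(x = "Distance to nearest rainbow-trout source (km)",
         y = "Probability of exceeding threshold",
         colour = "Mean August T (°C)",
         linetype = "Historical RT range") +
    theme_minimal()
}

#' Plot a habitat projection table
#'
#' Below-threshold habitat length by scenario, faceted by threshold and
#' coloured by range stratum.
#'
#' @param object a `habitat_projection` from [run_scenarios()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot habitat_projection
#' @export
autoplot.habitat_projection <- function(object, ...) {
  object$scenario <- factor(object$scenario, levels = unique(object$scenario))
  ggplot(object, aes(x = .data$scenario, y = .data$length_km,
                     fill = .data$stratum)) +
    geom_col(position = position_dodge()) +
    facet_wrap(~threshold, labeller = ggplot2::label_both) +
    labs(x = NULL, y = "Habitat below threshold (km)",
         fill = "RT range") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1))
}

#' Schematic plot of a stream network
#'
#' Draws each reach as a segment from its own coordinate to its downstream
#' neighbour's, line width scaled by flow; optionally coloured by an
#' attribute.
#'
#' @param net a `stream_network`.
#' @param colour_by name of a reach column to colour by (default
#'   temperature).
#' @return a ggplot.
#' @export
plot_network <- function(net, colour_by = "t_aug_c") {
  tab <- tibble::as_tibble(net)
  ends <- tab[c("reach_id", "easting_m", "northing_m")]
  names(ends) <- c("downstream_id", "end_e", "end_n")
  seg <- dplyr::inner_join(tab, ends, by = "downstream_id")
  ggplot(seg, aes(x = .data$easting_m, y = .data$northing_m,
                  xend = .data$end_e, yend = .data$end_n,
                  colour = .data[[colour_by]],
                  linewidth = .data$maf_cms)) +
    geom_segment(lineend = "round") +
    ggplot2::scale_linewidth(range = c(0.2, 2), guide = "none") +
    labs(x = "Easting (m)", y = "Northing (m)", colour = colour_by) +
    theme_minimal()
}
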