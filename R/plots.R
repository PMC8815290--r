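# Plotting: GPS week maps, IVF grids, and IRR forest plots.

#' Plot one labeled GPS week
#'
#' Fix positions colored by home/away label, with the home anchor marked;
#' a quick visual check of home anchoring and the home margin.
#'
#' @param labeled output of [classify_fixes()].
#' @param participant,visit which trace to draw.
#' @return a ggplot object.
#' @export
plot_gps_week <- function(labeled, participant, visit = "baseline") {
  df <- labeled[labeled$participant_id == participant &
                  labeled$visit == visit, , drop = FALSE]
  if (nrow(df) == 0) abort("no fixes for that participant/visit")
  home <- df[1, c("home_lat", "home_lon")]
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat,
                                   colour = .data$label)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::geom_point(data = home,
                        ggplot2::aes(.data$home_lon, .data$home_lat),
                        inherit.aes = FALSE, shape = 3, size = 3) +
    ggplot2::coord_quickmap() +
    ggplot2::labs(title = sprintf("%s, %s week", participant, visit),
                  x = "longitude", y = "latitude", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an integrated visual field
#'
#' Tile map of IVF point sensitivities in OD orientation (temporal field
#' to the right).
#'
#' @param ivf_points output of [integrate_fields()].
#' @param participant participant to draw.
#' @return a ggplot object.
#' @export
plot_ivf <- function(ivf_points, participant) {
  df <- ivf_points[ivf_points$participant_id == participant, , drop = FALSE]
  if (nrow(df) == 0) abort("no IVF points for that participant")
  ggplot2::ggplot(df, ggplot2::aes(.data$x_deg, .data$y_deg,
                                   fill = .data$sensitivity_db)) +
    ggplot2::geom_tile(width = 5.6, height = 5.6) +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$sensitivity_db)),
                       size = 2.6) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 40)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste("Integrated visual field,", participant),
                  x = "eccentricity x (deg)", y = "eccentricity y (deg)",
                  fill = "dB") +
    ggplot2::theme_minimal()
}

#' Forest plot of the IRR model grid
#'
#' @param irr_table output of [excursion_irr_table()].
#' @return a ggplot object.
#' @export
plot_irr_forest <- function(irr_table) {
  ggplot2::ggplot(irr_table,
                  ggplot2::aes(.data$irr, .data$exposure,
                               colour = .data$model)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_wrap(~outcome) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "IRR (95% CI, log scale)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.lifespacer_run <- function(object, ...) {
  plot_irr_forest(object$irr_table)
}
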