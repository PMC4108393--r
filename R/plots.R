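# ggplot2 displays for the main result types.

#' Plot an occupancy-abundance curve
#'
#' Mean occupancy (+/- 1 SD ribbon) against pack density, one panel per
#' survey-cell size.
#'
#' @param object An `occupancy_curve` from [run_curve()] (or any tibble
#'   with its columns).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot occupancy_curve
#' @export
autoplot.occupancy_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- paste0(df$month, ", ", df$hunting_units, " HU",
                     ifelse(df$loners, " + loners", ""))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$density, y = .data$mean_occupancy,
                                   colour = .data$label, fill = .data$label)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = pmax(.data$mean_occupancy - .data$sd_occupancy, 0),
      ymax = pmin(.data$mean_occupancy + .data$sd_occupancy, 1)
    ), alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~grid_km2, labeller = ggplot2::label_both) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Wolf pack density (packs / 1,000 km²)",
                  y = "Mean occupancy", colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot wolf paths over territories
#'
#' @param paths A path tibble.
#' @param layout Optional `territory_layout`; circles drawn as 90-gons.
#' @param grid Optional `survey_grid`; cell boundaries drawn.
#' @return A ggplot.
#' @export
plot_paths <- function(paths, layout = NULL, grid = NULL) {
  p <- ggplot2::ggplot()
  if (!is.null(grid)) {
    ex <- grid$extent
    p <- p +
      ggplot2::geom_vline(xintercept = seq(ex[["xmin"]], ex[["xmax"]],
                                           by = grid$cell_side_m),
                          colour = "grey85", linewidth = 0.2) +
      ggplot2::geom_hline(yintercept = seq(ex[["ymin"]], ex[["ymax"]],
                                           by = grid$cell_side_m),
                          colour = "grey85", linewidth = 0.2)
  }
  if (!is.null(layout) && nrow(layout) > 0) {
    ang <- seq(0, 2 * pi, length.out = 91)
    circ <- purrr::map_dfr(seq_len(nrow(layout)), function(i) {
      tibble::tibble(pack_id = layout$pack_id[i],
                     x_m = layout$cx[i] + layout$radius_m[i] * cos(ang),
                     y_m = layout$cy[i] + layout$radius_m[i] * sin(ang))
    })
    p <- p + ggplot2::geom_path(
      data = circ,
      ggplot2::aes(.data$x_m, .data$y_m, group = .data$pack_id),
      colour = "steelblue", linewidth = 0.3
    )
  }
  p +
    ggplot2::geom_path(
      data = paths,
      ggplot2::aes(.data$x_m, .data$y_m, group = .data$path_id),
      colour = "grey20", linewidth = 0.3
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

#' Plot a habitat-quality surface
#'
#' @param raster A `landscape_raster`.
#' @return A ggplot raster map of habitat weights.
#' @export
plot_landscape <- function(raster) {
  df <- as_tibble(raster)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_m, .data$y_m, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = "Habitat\nweight") +
    ggplot2::theme_minimal()
}
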