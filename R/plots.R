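# ggplot2 views of the package's result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_col
#'   geom_point geom_errorbar facet_wrap labs scale_fill_viridis_c
#'   coord_fixed theme_minimal
#' @export
ggplot2::autoplot

#' Plot a climate grid
#'
#' One raster panel per bioclim band.
#'
#' @param object A `climate_grid`.
#' @param bands Bands to draw (default all five).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.climate_grid <- function(object, bands = bioclim_vars(), ...) {
  long <- tidyr::pivot_longer(as_tibble(object)[, c("lon", "lat", bands)],
                              dplyr::all_of(bands),
                              names_to = "band", values_to = "value")
  ggplot(long, aes(.data$lon, .data$lat, fill = .data$value)) +
    geom_raster() +
    facet_wrap(~band, scales = "free") +
    scale_fill_viridis_c() +
    coord_fixed() +
    labs(x = "Longitude", y = "Latitude",
         title = sprintf("Climate grid (%s)", format(grid_scenario(object)))) +
    theme_minimal()
}

#' Plot an occupancy or suitability surface
#'
#' @param object An `occupancy_surface` or `suitability_surface`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.suitability_surface <- function(object, ...) {
  ggplot(object, aes(.data$lon, .data$lat, fill = .data$probability)) +
    geom_raster() +
    scale_fill_viridis_c(limits = c(0, 1)) +
    coord_fixed() +
    labs(x = "Longitude", y = "Latitude", fill = "P(occurrence)",
         title = sprintf("%s suitability (%s)",
                         attr(object, "algorithm") %||% "",
                         format(grid_scenario(object)))) +
    theme_minimal()
}

#' @rdname autoplot.suitability_surface
#' @export
autoplot.occupancy_surface <- function(object, ...) {
  ggplot(object, aes(.data$lon, .data$lat, fill = .data$occupancy)) +
    geom_raster() +
    scale_fill_viridis_c(limits = c(0, 1)) +
    coord_fixed() +
    labs(x = "Longitude", y = "Latitude", fill = "Occupancy",
         title = "True occupancy") +
    theme_minimal()
}

#' Plot a partial response curve
#'
#' @param object A [response_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.response_curve <- function(object, ...) {
  ggplot(object, aes(.data$value, .data$probability)) +
    geom_line() +
    labs(x = object$variable[1], y = "Partial probability of occurrence",
         title = sprintf("%s response (%s)", object$variable[1],
                         attr(object, "algorithm"))) +
    theme_minimal()
}

#' Plot delta-AUC variable importance
#'
#' @param object A [delta_auc_importance()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.variable_importance <- function(object, ...) {
  ggplot(object, aes(stats::reorder(.data$variable, -.data$delta_auc),
                     .data$delta_auc)) +
    geom_col() +
    labs(x = NULL, y = "Delta AUC",
         title = sprintf("Variable importance (%s)", attr(object, "algorithm"))) +
    theme_minimal()
}

#' Plot a scenario range table
#'
#' Mean suitable area with min-max member range, by RCP and year.
#'
#' @param object A `range_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.range_table <- function(object, ...) {
  fut <- object[!is.na(object$rcp), ]
  ggplot(fut, aes(factor(.data$rcp), .data$mean_area_km2)) +
    geom_col() +
    geom_errorbar(aes(ymin = .data$area_min, ymax = .data$area_max),
                  width = 0.2) +
    facet_wrap(~year) +
    labs(x = "RCP", y = "Suitable area (km²)",
         title = "Projected suitable range by scenario") +
    theme_minimal()
}
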