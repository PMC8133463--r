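# Projection of fitted envelopes over climate grids, max-kappa
# binarisation, latitude-corrected areas, GCM x algorithm ensembling, and
# the per-scenario range summary (mean / min / max area and percent-left).

#' Project a fitted model over a climate grid
#'
#' Predicts probability of occurrence for every grid cell. Cells with any
#' missing band value get `NA` and are excluded from all downstream area
#' computations.
#'
#' @param model An `sdm_model`.
#' @param grid A `climate_grid` carrying the model's covariate bands.
#' @return A `suitability_surface` tibble (`lon`, `lat`, `probability`) with
#'   algorithm and scenario provenance attributes.
#' @export
project_surface <- function(model, grid) {
  assert_has_cols(grid, model$covariates, "grid")
  data <- as_tibble(grid)
  complete <- stats::complete.cases(data[, model$covariates])
  p <- rep(NA_real_, nrow(data))
  if (any(complete)) {
    p[complete] <- predict(model, data[complete, ])
  }
  out <- new_grid_tbl(tibble(lon = data$lon, lat = data$lat, probability = p),
                      grid_resolution(grid), grid_extent(grid),
                      grid_scenario(grid), "suitability_surface")
  attr(out, "algorithm") <- model$algorithm$id
  out
}

#' Binarise a suitability surface at a threshold
#'
#' A cell is suitable iff its probability is greater than or equal to the
#' threshold; `NA` cells stay `NA`.
#'
#' @param surface A `suitability_surface`.
#' @param threshold Probability threshold in `[0, 1]`.
#' @return A `range_mask` tibble (`lon`, `lat`, `presence` in {0, 1, NA}).
#' @export
binarize <- function(surface, threshold) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    rlang::abort("`threshold` must be in [0, 1]",
                 class = "climenvelope_config_error")
  }
  out <- new_grid_tbl(
    tibble(lon = surface$lon, lat = surface$lat,
           presence = as.integer(surface$probability >= threshold)),
    grid_resolution(surface), grid_extent(surface), grid_scenario(surface),
    "range_mask")
  attr(out, "threshold") <- threshold
  attr(out, "algorithm") <- attr(surface, "algorithm")
  out
}

#' Area of a binary range mask in km^2
#'
#' Cell areas use the cosine-latitude rectangle approximation:
#' `(r K) * (r K cos(lat))` with `r` the resolution in degrees and
#' `K = 111.32` km per degree. At tropical latitudes this is within 0.3% of
#' the exact spherical cell area.
#'
#' @param mask A `range_mask`.
#' @return Total suitable area in km^2 (0 for an empty mask).
#' @export
mask_area_km2 <- function(mask) {
  r <- grid_resolution(mask)
  on <- !is.na(mask$presence) & mask$presence == 1L
  if (!any(on)) return(0)
  cell <- (r * KM_PER_DEGREE) * (r * KM_PER_DEGREE * cos(mask$lat[on] * pi / 180))
  sum(cell)
}

#' Cell-wise mean of suitability surfaces
#'
#' Arithmetic mean across surfaces with identical geometry — the ensemble
#' map averaged over GCMs and algorithms. `NA` at a cell in any member
#' propagates to the mean.
#'
#' @param surfaces List of `suitability_surface` objects.
#' @return A `suitability_surface`.
#' @export
ensemble_mean_surface <- function(surfaces) {
  stopifnot(length(surfaces) >= 1)
  ref <- surfaces[[1]]
  for (s in surfaces[-1]) {
    if (!same_geometry(ref, s)) {
      rlang::abort("surfaces have mismatching geometry",
                   class = "climenvelope_schema_error")
    }
  }
  probs <- vapply(surfaces, function(s) s$probability,
                  numeric(nrow(ref)))
  p <- rowMeans(matrix(probs, nrow = nrow(ref)))
  out <- new_grid_tbl(tibble(lon = ref$lon, lat = ref$lat, probability = p),
                      grid_resolution(ref), grid_extent(ref),
                      grid_scenario(ref), "suitability_surface")
  attr(out, "algorithm") <- "ensemble"
  out
}

#' Percent of current range left under a scenario
#'
#' `round(100 * future / current)`, rounding half up to the printed integer.
#'
#' @param future_area_km2,current_area_km2 Areas in km^2; the current area
#'   must be positive.
#' @return Integer percentage.
#' @export
percent_left <- function(future_area_km2, current_area_km2) {
  if (any(current_area_km2 <= 0)) {
    rlang::abort("current area must be positive",
                 class = "climenvelope_degenerate_error")
  }
  as.integer(floor(100 * future_area_km2 / current_area_km2 + 0.5))
}

#' Scenario range summary table
#'
#' The per-scenario analogue of a published range-projection table: for each
#' RCP x year, the suitable area per (algorithm x GCM) member, their mean,
#' min and max, and the percent of the mean current simulated range left.
#' Every scenario is binarised with the algorithm's max-kappa threshold
#' derived under current conditions (threshold transfer is asserted here:
#' one current-condition threshold per algorithm is used for every
#' scenario). The current simulated range is the mean over algorithms of the
#' current binarised areas.
#'
#' @param models Named list of refitted `sdm_model`s (names = algorithm ids).
#' @param thresholds Named list of [max_kappa_threshold()] results (or bare
#'   numeric thresholds), names matching `models`; each must come from the
#'   current-condition surface.
#' @param future_grids List of `climate_grid`s with future
#'   [scenario_future()] metadata (one per GCM x RCP x year).
#' @param current_grid The current-condition `climate_grid`.
#' @return A `range_table` tibble with one row per scenario (plus a
#'   `"current"` row): `scenario`, `rcp`, `year`, `mean_area_km2`,
#'   `area_min`, `area_max`, `percent_left`, `percent_min`, `percent_max`.
#' @export
scenario_range_table <- function(models, thresholds, future_grids,
                                 current_grid) {
  if (!setequal(names(models), names(thresholds))) {
    rlang::abort("`models` and `thresholds` must carry the same algorithm names",
                 class = "climenvelope_config_error")
  }
  thr <- vapply(names(models), function(a) {
    t <- thresholds[[a]]
    if (inherits(t, "threshold_result")) t <- t$threshold
    if (!is.numeric(t) || t < 0 || t > 1) {
      rlang::abort(sprintf("threshold for %s is not a probability", a),
                   class = "climenvelope_config_error")
    }
    t
  }, numeric(1))

  current_areas <- vapply(names(models), function(a) {
    mask_area_km2(binarize(project_surface(models[[a]], current_grid), thr[[a]]))
  }, numeric(1))
  current_mean <- mean(current_areas)

  members <- purrr::map_dfr(future_grids, function(g) {
    sc <- grid_scenario(g)
    if (identical(sc$label, "current")) {
      rlang::abort("future grid carries the 'current' scenario",
                   class = "climenvelope_config_error")
    }
    purrr::map_dfr(names(models), function(a) {
      area <- mask_area_km2(binarize(project_surface(models[[a]], g), thr[[a]]))
      tibble(algorithm = a, gcm = sc$gcm, rcp = sc$rcp, year = sc$year,
             area_km2 = area)
    })
  })

  summary <- if (nrow(members)) {
    members %>%
      dplyr::group_by(.data$rcp, .data$year) %>%
      dplyr::summarise(
        mean_area_km2 = mean(.data$area_km2),
        area_min = min(.data$area_km2),
        area_max = max(.data$area_km2),
        .groups = "drop") %>%
      dplyr::mutate(
        scenario = sprintf("Year %d, RCP %.1f", .data$year, .data$rcp),
        percent_left = percent_left(.data$mean_area_km2, current_mean),
        percent_min = percent_left(.data$area_min, current_mean),
        percent_max = percent_left(.data$area_max, current_mean)) %>%
      dplyr::arrange(.data$year, .data$rcp)
  } else NULL

  out <- dplyr::bind_rows(
    tibble(scenario = "Current", rcp = NA_real_, year = NA_integer_,
           mean_area_km2 = current_mean,
           area_min = min(current_areas), area_max = max(current_areas),
           percent_left = NA_integer_, percent_min = NA_integer_,
           percent_max = NA_integer_),
    summary)[, c("scenario", "rcp", "year", "mean_area_km2", "area_min",
                 "area_max", "percent_left", "percent_min", "percent_max")]
  attr(out, "members") <- members
  attr(out, "current_areas") <- current_areas
  attr(out, "thresholds") <- thr
  class(out) <- c("range_table", class(tibble()))
  out
}

#' Per-member areas behind a range table
#'
#' @param x A `range_table`.
#' @return Tibble of per-(algorithm x GCM x scenario) areas.
#' @export
range_table_members <- function(x) attr(x, "members")
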