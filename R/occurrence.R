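# Assembly of the model-fitting dataset: presences, transect-derived
# absences, and spatially constrained pseudo-absences, with covariate
# extraction from a climate grid.

#' Absence records at the midpoints of undetected transects
#'
#' Each transect on which the species was not recorded contributes one
#' absence record at the great-circle midpoint of its endpoints; detected
#' transects contribute nothing.
#'
#' @param transects Tibble with columns `lon1`, `lat1`, `lon2`, `lat2`,
#'   `detected` (see [simulate_transects()]).
#' @return A tibble of occurrence records: `lon`, `lat`, `label`
#'   (`"absence"`), `source` (`"transect_midpoint"`).
#' @export
transect_absence_midpoints <- function(transects) {
  assert_has_cols(transects, c("lon1", "lat1", "lon2", "lat2", "detected"),
                  "transects")
  un <- dplyr::filter(transects, !.data$detected)
  if (nrow(un) == 0) {
    return(tibble(lon = numeric(), lat = numeric(),
                  label = character(), source = character()))
  }
  mid <- geodesic_midpoint(un$lon1, un$lat1, un$lon2, un$lat2)
  tibble(lon = mid$lon, lat = mid$lat,
         label = "absence", source = "transect_midpoint")
}

#' Sample pseudo-absence background points
#'
#' Draws `n` points uniformly over a lon/lat rectangle by rejection
#' sampling, keeping only points at great-circle (haversine) distance of at
#' least `min_dist_km` from every presence location. The distance buffer
#' applies to presences only, not to transect absences.
#'
#' @param region Named numeric `lon_min`, `lon_max`, `lat_min`, `lat_max`.
#' @param presences Tibble with `lon`, `lat` columns (may have zero rows).
#' @param n Number of pseudo-absences.
#' @param min_dist_km Exclusion radius around each presence, km.
#' @param seed Integer seed.
#' @param max_tries Proposal budget before declaring the sampling
#'   infeasible; defaults to `1000 * n`.
#' @return A tibble of occurrence records: `lon`, `lat`, `label`
#'   (`"pseudo_absence"`), `source` (`"random_background"`).
#' @export
sample_pseudo_absences <- function(region, presences, n, min_dist_km = 10,
                                   seed = 1L, max_tries = 1000 * n) {
  if (region[["lon_min"]] >= region[["lon_max"]] ||
      region[["lat_min"]] >= region[["lat_max"]]) {
    rlang::abort("`region` is degenerate", class = "climenvelope_config_error")
  }
  if (min_dist_km < 0) {
    rlang::abort("`min_dist_km` must be >= 0", class = "climenvelope_config_error")
  }
  empty <- tibble(lon = numeric(), lat = numeric(),
                  label = character(), source = character())
  if (n == 0) return(empty)
  keep_lon <- numeric(0); keep_lat <- numeric(0)
  tries <- 0
  withr::with_seed(seed, {
    while (length(keep_lon) < n && tries < max_tries) {
      m <- min(max(2L * (n - length(keep_lon)), 100L), 20000L)
      tries <- tries + m
      lon <- runif(m, region[["lon_min"]], region[["lon_max"]])
      lat <- runif(m, region[["lat_min"]], region[["lat_max"]])
      ok <- rep(TRUE, m)
      if (nrow(presences) > 0 && min_dist_km > 0) {
        # minimum distance to any presence, chunked over candidates
        dmin <- vapply(seq_len(m), function(i) {
          min(haversine_km(lon[i], lat[i], presences$lon, presences$lat))
        }, numeric(1))
        ok <- dmin >= min_dist_km
      }
      keep_lon <- c(keep_lon, lon[ok])
      keep_lat <- c(keep_lat, lat[ok])
    }
  })
  if (length(keep_lon) < n) {
    rlang::abort(sprintf(
      "could only place %d of %d pseudo-absences within the attempt budget; exclusion zones may cover the region",
      length(keep_lon), n), class = "climenvelope_infeasible_error")
  }
  tibble(lon = keep_lon[seq_len(n)], lat = keep_lat[seq_len(n)],
         label = "pseudo_absence", source = "random_background")
}

#' Assemble the model-fitting feature table
#'
#' Combines presences, transect absences and pseudo-absences, extracts the
#' five covariate values from the climate-grid cell containing each point
#' (no interpolation; a point exactly on a cell corner goes to the cell to
#' its north-east), and codes the binary response: 1 for presences, 0 for
#' absences and pseudo-absences. Points falling off the grid are dropped
#' with a message giving the count. Row order is presences, absences,
#' pseudo-absences.
#'
#' @param presences Tibble of `lon`, `lat` presence points.
#' @param transect_absences Records from [transect_absence_midpoints()].
#' @param pseudo_absences Records from [sample_pseudo_absences()].
#' @param grid A `climate_grid` covering the points.
#' @return A feature-table tibble with columns `lon`, `lat`, `label`,
#'   `source`, `response` and the five [bioclim_vars()].
#' @export
assemble_training_set <- function(presences, transect_absences,
                                  pseudo_absences, grid) {
  assert_has_cols(grid, bioclim_vars(), "grid")
  pres <- tibble(lon = presences$lon, lat = presences$lat,
                 label = "presence",
                 source = if ("source" %in% names(presences))
                   presences$source else "sighting")
  pts <- dplyr::bind_rows(pres,
                          transect_absences[, c("lon", "lat", "label", "source")],
                          pseudo_absences[, c("lon", "lat", "label", "source")])
  idx <- cell_index(pts$lon, pts$lat, grid_extent(grid), grid_resolution(grid))
  n_drop <- sum(is.na(idx))
  if (n_drop > 0) {
    rlang::inform(sprintf("dropping %d point(s) falling outside the climate grid", n_drop))
  }
  keep <- !is.na(idx)
  if (!any(keep)) {
    rlang::abort("all points fall outside the climate grid",
                 class = "climenvelope_empty_table_error")
  }
  pts <- pts[keep, ]
  cov <- as_tibble(grid)[idx[keep], bioclim_vars()]
  out <- dplyr::bind_cols(
    pts,
    tibble(response = as.integer(pts$label == "presence")),
    cov)
  out <- out[, c("lon", "lat", "label", "source", "response", bioclim_vars())]
  attr(out, "n_dropped") <- n_drop
  out
}

#' Read / write occurrence point CSV
#'
#' Plain CSV with columns `lon`, `lat`, `label`, `source`.
#'
#' @param points A tibble of occurrence records.
#' @param path File path.
#' @return `read_points_csv()` returns a tibble; `write_points_csv()`
#'   returns `path` invisibly.
#' @export
write_points_csv <- function(points, path) {
  readr::write_csv(points, path)
  invisible(path)
}

#' @rdname write_points_csv
#' @export
read_points_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
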