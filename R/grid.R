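# Climate grids and derived surfaces are long-format tibbles: one row per
# cell centre (lon, lat) plus value columns, carrying geometry (extent,
# resolution) and scenario metadata as attributes. Cell centres are laid out
# row-major, south to north, west to east, so geometry comparisons are exact.

#' Scenario descriptors
#'
#' A scenario is either the distinguished value `"current"` or a
#' GCM / RCP / year triple describing a future climate projection.
#'
#' @param gcm GCM identifier (character).
#' @param rcp Representative Concentration Pathway, one of 2.6, 4.5, 6.0, 8.5.
#' @param year Projection year, 2050 or 2070.
#' @return A `scenario_spec` list with fields `label`, `gcm`, `rcp`, `year`.
#' @export
scenario_current <- function() {
  structure(list(label = "current", gcm = NA_character_,
                 rcp = NA_real_, year = NA_integer_),
            class = "scenario_spec")
}

#' @rdname scenario_current
#' @export
scenario_future <- function(gcm, rcp, year) {
  if (!rcp %in% c(2.6, 4.5, 6.0, 8.5)) {
    rlang::abort("`rcp` must be one of 2.6, 4.5, 6.0, 8.5",
                 class = "climenvelope_config_error")
  }
  if (!year %in% c(2050L, 2070L)) {
    rlang::abort("`year` must be 2050 or 2070",
                 class = "climenvelope_config_error")
  }
  structure(list(label = sprintf("%s_rcp%.1f_%d", gcm, rcp, year),
                 gcm = as.character(gcm), rcp = as.numeric(rcp),
                 year = as.integer(year)),
            class = "scenario_spec")
}

#' @exportS3Method base::format
format.scenario_spec <- function(x, ...) {
  if (identical(x$label, "current")) "current"
  else sprintf("%s / RCP%.1f / %d", x$gcm, x$rcp, x$year)
}

#' @exportS3Method base::print
print.scenario_spec <- function(x, ...) {
  cat("<scenario>", format(x), "\n")
  invisible(x)
}

new_grid_tbl <- function(data, resolution, extent, scenario, class) {
  out <- as_tibble(data)
  attr(out, "resolution") <- resolution
  attr(out, "extent") <- extent
  attr(out, "scenario") <- scenario
  class(out) <- c(class, class(tibble()))
  out
}

#' Geometry accessors for grids and surfaces
#'
#' @param x A `climate_grid`, `occupancy_surface`, `suitability_surface` or
#'   `range_mask`.
#' @return `grid_resolution()`: cell size in degrees. `grid_extent()`: named
#'   vector `lon_min, lon_max, lat_min, lat_max`. `grid_scenario()`: the
#'   attached [scenario_current()] / [scenario_future()] descriptor.
#' @export
grid_resolution <- function(x) attr(x, "resolution")

#' @rdname grid_resolution
#' @export
grid_extent <- function(x) attr(x, "extent")

#' @rdname grid_resolution
#' @export
grid_scenario <- function(x) attr(x, "scenario")

same_geometry <- function(a, b) {
  isTRUE(all.equal(grid_resolution(a), grid_resolution(b))) &&
    isTRUE(all.equal(grid_extent(a), grid_extent(b))) &&
    nrow(a) == nrow(b) &&
    isTRUE(all.equal(a$lon, b$lon)) &&
    isTRUE(all.equal(a$lat, b$lat))
}

# cell centres for an extent/resolution, row-major south->north
grid_centres <- function(extent, resolution) {
  nx <- round((extent[["lon_max"]] - extent[["lon_min"]]) / resolution)
  ny <- round((extent[["lat_max"]] - extent[["lat_min"]]) / resolution)
  lons <- extent[["lon_min"]] + (seq_len(nx) - 0.5) * resolution
  lats <- extent[["lat_min"]] + (seq_len(ny) - 0.5) * resolution
  tidyr::expand_grid(lat = lats, lon = lons)[, c("lon", "lat")]
}

# map points to 1-based cell index in the row-major layout; a point exactly
# on an interior cell boundary is assigned to the cell to its north-east;
# points outside [min, max) on either axis get NA
cell_index <- function(lon, lat, extent, resolution) {
  nx <- round((extent[["lon_max"]] - extent[["lon_min"]]) / resolution)
  ny <- round((extent[["lat_max"]] - extent[["lat_min"]]) / resolution)
  ix <- floor((lon - extent[["lon_min"]]) / resolution) + 1
  iy <- floor((lat - extent[["lat_min"]]) / resolution) + 1
  bad <- ix < 1 | ix > nx | iy < 1 | iy > ny
  idx <- (iy - 1) * nx + ix
  idx[bad] <- NA_integer_
  as.integer(idx)
}

#' @exportS3Method base::print
print.climate_grid <- function(x, ...) {
  ext <- grid_extent(x)
  cat(sprintf(
    "<climate_grid> %d cells @ %.4f deg | lon [%.2f, %.2f] lat [%.2f, %.2f] | scenario: %s\n",
    nrow(x), grid_resolution(x), ext[["lon_min"]], ext[["lon_max"]],
    ext[["lat_min"]], ext[["lat_max"]], format(grid_scenario(x))))
  NextMethod()
}

#' Write / read a climate grid as CSV
#'
#' Grids are stored as plain CSV (one row per cell) with geometry and
#' scenario metadata in `#`-prefixed header lines, so a round trip preserves
#' the full object. No binary raster format is used.
#'
#' @param grid A `climate_grid`.
#' @param path File path.
#' @return `write_grid_csv()` returns `path` invisibly; `read_grid_csv()`
#'   returns a `climate_grid`.
#' @export
write_grid_csv <- function(grid, path) {
  ext <- grid_extent(grid)
  sc <- grid_scenario(grid)
  meta <- c(
    sprintf("# resolution: %.10g", grid_resolution(grid)),
    sprintf("# extent: %.10g %.10g %.10g %.10g",
            ext[["lon_min"]], ext[["lon_max"]], ext[["lat_min"]], ext[["lat_max"]]),
    sprintf("# scenario: %s|%s|%s", sc$gcm, sc$rcp, sc$year)
  )
  writeLines(meta, path)
  readr::write_csv(as_tibble(grid), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  hdr <- readLines(path, n = 3L)
  res <- as.numeric(sub("# resolution: ", "", hdr[1]))
  ev <- as.numeric(strsplit(sub("# extent: ", "", hdr[2]), " ")[[1]])
  extent <- c(lon_min = ev[1], lon_max = ev[2], lat_min = ev[3], lat_max = ev[4])
  sv <- strsplit(sub("# scenario: ", "", hdr[3]), "|", fixed = TRUE)[[1]]
  scenario <- if (sv[1] == "NA") scenario_current()
              else scenario_future(sv[1], as.numeric(sv[2]), as.integer(sv[3]))
  data <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  new_grid_tbl(data, res, extent, scenario, "climate_grid")
}
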