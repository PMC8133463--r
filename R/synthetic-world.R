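# Synthetic stated world: a cool-dry core region inside a hotter, wetter
# surround, with occupancy limited by upper thresholds on maximum temperature
# and dry-season precipitation. Emulates the statistical structure the
# analysis assumes (spatially autocorrelated covariate fields, threshold-
# limited occupancy) without any external climate download.

#' Configuration of the synthetic world
#'
#' Bundles every knob of the synthetic-data generator. Defaults describe a
#' 4 x 3 degree tropical window at 0.05 degree resolution with a cool-dry
#' core, an occupancy ceiling at 33 degrees C maximum temperature and 60 mm
#' dry-season precipitation (the middle of the 30-35 degC / 50-70 mm ranges
#' the envelope is meant to recover), 500 presence records and 255 walked
#' 1-km transects.
#'
#' @param extent Named numeric: `lon_min`, `lon_max`, `lat_min`, `lat_max`
#'   (decimal degrees).
#' @param resolution Cell size in degrees.
#' @param core_center Named numeric `lon`, `lat`: centre of the cool-dry core.
#' @param temp_threshold Occupancy threshold T0 on maximum temperature (degC).
#' @param temp_softness Logistic softness sT of the temperature threshold (degC).
#' @param precip_threshold Occupancy threshold P0 on dry-quarter
#'   precipitation (mm).
#' @param precip_softness Logistic softness sP of the precipitation
#'   threshold (mm).
#' @param temp_core,temp_gradient Max-temperature at the core (degC) and its
#'   radial increase (degC per degree of distance).
#' @param precip_dry_core,precip_dry_gradient Dry-quarter precipitation at
#'   the core (mm) and its radial increase (mm per degree).
#' @param field_smoothing_scale Gaussian smoothing length of the noise
#'   fields, in cells.
#' @param noise_sd Named numeric of per-band noise standard deviations
#'   (after smoothing), one per [bioclim_vars()].
#' @param n_presence Number of presence points to sample.
#' @param n_transects Number of walked transects.
#' @param transect_length_km Transect length (km).
#' @param detection_prob Per-transect detection probability multiplier in
#'   (0, 1].
#' @param seed Integer seed; mandatory for reproducibility.
#' @return A `synthetic_world_config` list.
#' @export
synthetic_world_config <- function(
    extent = c(lon_min = 36, lon_max = 40, lat_min = 3.5, lat_max = 6.5),
    resolution = 0.05,
    core_center = c(lon = 38, lat = 5),
    temp_threshold = 33, temp_softness = 1,
    precip_threshold = 60, precip_softness = 8,
    temp_core = 28, temp_gradient = 3.5,
    precip_dry_core = 25, precip_dry_gradient = 25,
    field_smoothing_scale = 3,
    noise_sd = c(bio_maxtemp = 0.6, bio_tseason = 30, bio_trange = 0.4,
                 bio_pwet = 15, bio_pdry = 4),
    n_presence = 500, n_transects = 255, transect_length_km = 1,
    detection_prob = 0.6,
    seed = 1L) {
  cfg <- list(
    extent = extent, resolution = resolution, core_center = core_center,
    temp_threshold = temp_threshold, temp_softness = temp_softness,
    precip_threshold = precip_threshold, precip_softness = precip_softness,
    temp_core = temp_core, temp_gradient = temp_gradient,
    precip_dry_core = precip_dry_core,
    precip_dry_gradient = precip_dry_gradient,
    field_smoothing_scale = field_smoothing_scale,
    noise_sd = noise_sd,
    n_presence = n_presence, n_transects = n_transects,
    transect_length_km = transect_length_km,
    detection_prob = detection_prob,
    seed = as.integer(seed))
  class(cfg) <- "synthetic_world_config"
  validate_world_config(cfg)
}

validate_world_config <- function(cfg) {
  problems <- character()
  ext <- cfg$extent
  if (!all(c("lon_min", "lon_max", "lat_min", "lat_max") %in% names(ext)) ||
      ext[["lon_min"]] >= ext[["lon_max"]] ||
      ext[["lat_min"]] >= ext[["lat_max"]]) {
    problems <- c(problems, "`extent` must satisfy lon_min < lon_max and lat_min < lat_max")
  }
  if (!is.numeric(cfg$resolution) || cfg$resolution <= 0)
    problems <- c(problems, "`resolution` must be > 0")
  if (cfg$temp_softness <= 0) problems <- c(problems, "`temp_softness` must be > 0")
  if (cfg$precip_softness <= 0) problems <- c(problems, "`precip_softness` must be > 0")
  if (cfg$detection_prob <= 0 || cfg$detection_prob > 1)
    problems <- c(problems, "`detection_prob` must be in (0, 1]")
  if (!setequal(names(cfg$noise_sd), bioclim_vars()))
    problems <- c(problems, "`noise_sd` must name all five bioclim bands")
  if (length(problems)) {
    rlang::abort(c("invalid synthetic world configuration", problems),
                 class = "climenvelope_config_error")
  }
  cfg
}

# Gaussian-smooth a matrix with a separable kernel; edges renormalised so a
# constant field stays constant
smooth_field <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  half <- ceiling(3 * sigma)
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  pass <- function(m) {
    acc <- matrix(0, nrow(m), ncol(m))
    wgt <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k)) {
      off <- j - half - 1
      src <- seq_len(nrow(m)) + off
      ok <- src >= 1 & src <= nrow(m)
      acc[ok, ] <- acc[ok, ] + k[j] * m[src[ok], ]
      wgt[ok, ] <- wgt[ok, ] + k[j]
    }
    acc / wgt
  }
  t(pass(t(pass(mat))))
}

# smoothed Gaussian noise field rescaled to a target marginal sd
noise_field <- function(nx, ny, sigma, sd_target) {
  if (sd_target <= 0) return(matrix(0, ny, nx))
  raw <- matrix(rnorm(nx * ny), ny, nx)
  sm <- smooth_field(raw, sigma)
  s <- stats::sd(as.vector(sm))
  if (s == 0) return(matrix(0, ny, nx))
  sm * (sd_target / s)
}

#' Generate the synthetic five-band climate grid
#'
#' Builds the five bioclim covariate surfaces over the configured extent:
#' maximum temperature of the warmest month has its minimum at the core and
#' rises radially away from it, dry-quarter precipitation likewise increases
#' away from the core, and the remaining three bands are smooth nuisance
#' fields (mild linear gradients plus smoothed noise) that play no role in
#' occupancy. Deterministic given `config$seed`.
#'
#' @param config A [synthetic_world_config()].
#' @return A `climate_grid` tibble with columns `lon`, `lat` and the five
#'   [bioclim_vars()].
#' @export
generate_climate_grid <- function(config) {
  config <- validate_world_config(config)
  ext <- config$extent
  res <- config$resolution
  cells <- grid_centres(ext, res)
  nx <- length(unique(cells$lon)); ny <- length(unique(cells$lat))
  dx <- cells$lon - config$core_center[["lon"]]
  dy <- cells$lat - config$core_center[["lat"]]
  d <- sqrt(dx^2 + dy^2)
  # precipitation uses an anisotropic, rotated distance so the two governing
  # fields both rise away from the core without being collinear (the fitted
  # envelope could not otherwise attribute the decline between them)
  du <- (dx + dy) / sqrt(2)
  dv <- (dy - dx) / sqrt(2)
  d_p <- sqrt(1.8 * du^2 + 0.2 * dv^2)
  u <- (cells$lon - ext[["lon_min"]]) / (ext[["lon_max"]] - ext[["lon_min"]])
  v <- (cells$lat - ext[["lat_min"]]) / (ext[["lat_max"]] - ext[["lat_min"]])
  sds <- config$noise_sd
  withr::with_seed(config$seed, {
    nz <- lapply(bioclim_vars(), function(b)
      as.vector(t(noise_field(nx, ny, config$field_smoothing_scale, sds[[b]]))))
    names(nz) <- bioclim_vars()
    data <- tibble(
      lon = cells$lon, lat = cells$lat,
      bio_maxtemp = config$temp_core + config$temp_gradient * d + nz$bio_maxtemp,
      bio_tseason = 1200 + 150 * u + nz$bio_tseason,
      bio_trange  = 14 + 2 * v + nz$bio_trange,
      bio_pwet    = 300 + 80 * (1 - u) + nz$bio_pwet,
      bio_pdry    = config$precip_dry_core + config$precip_dry_gradient * d_p +
                    nz$bio_pdry
    )
  })
  new_grid_tbl(data, res, ext, scenario_current(), "climate_grid")
}

#' True occupancy surface of the synthetic world
#'
#' Per cell, the probability of occurrence is the product of two logistic
#' threshold responses,
#' `p = plogis((T0 - T)/sT) * plogis((P0 - P)/sP)`,
#' so occupancy collapses to zero wherever maximum temperature or dry-quarter
#' precipitation sits far above its threshold, while remaining smooth enough
#' for likelihood-based fitting. This is the ground truth that
#' parameter-recovery tests compare against.
#'
#' @param grid A `climate_grid` containing `bio_maxtemp` and `bio_pdry`.
#' @param config A [synthetic_world_config()] supplying T0, sT, P0, sP.
#' @return An `occupancy_surface` tibble with columns `lon`, `lat`,
#'   `occupancy`.
#' @export
true_occupancy <- function(grid, config) {
  assert_has_cols(grid, c("bio_maxtemp", "bio_pdry"), "grid")
  p <- plogis((config$temp_threshold - grid$bio_maxtemp) / config$temp_softness) *
       plogis((config$precip_threshold - grid$bio_pdry) / config$precip_softness)
  new_grid_tbl(tibble(lon = grid$lon, lat = grid$lat, occupancy = p),
               grid_resolution(grid), grid_extent(grid), grid_scenario(grid),
               "occupancy_surface")
}

#' Sample presence points from an occupancy surface
#'
#' Cells are drawn with probability proportional to occupancy and each point
#' is jittered uniformly within its cell, standing in for field sighting and
#' nest records.
#'
#' @param surface An `occupancy_surface`.
#' @param n Number of points.
#' @param seed Integer seed.
#' @return A tibble of `lon`, `lat` presence points.
#' @export
sample_presences <- function(surface, n, seed) {
  if (n == 0) return(tibble(lon = numeric(), lat = numeric()))
  if (all(surface$occupancy <= 0)) {
    rlang::abort("occupancy surface has no cell with positive probability",
                 class = "climenvelope_unsampleable_error")
  }
  res <- grid_resolution(surface)
  withr::with_seed(seed, {
    idx <- sample.int(nrow(surface), n, replace = TRUE,
                      prob = surface$occupancy)
    tibble(
      lon = surface$lon[idx] + runif(n, -res / 2, res / 2),
      lat = surface$lat[idx] + runif(n, -res / 2, res / 2)
    )
  })
}

# nearest-cell occupancy lookup, clamped to the grid edge
occupancy_at <- function(surface, lon, lat) {
  ext <- grid_extent(surface); res <- grid_resolution(surface)
  nx <- round((ext[["lon_max"]] - ext[["lon_min"]]) / res)
  ny <- round((ext[["lat_max"]] - ext[["lat_min"]]) / res)
  ix <- pmin(pmax(floor((lon - ext[["lon_min"]]) / res) + 1, 1), nx)
  iy <- pmin(pmax(floor((lat - ext[["lat_min"]]) / res) + 1, 1), ny)
  surface$occupancy[(iy - 1) * nx + ix]
}

#' Simulate walked detection transects
#'
#' Transect start points are placed by stratified random sampling over a
#' regular macro-grid (so some transects fall outside the core range), each
#' transect is a straight 1-km segment with uniform random bearing, and the
#' detection flag is Bernoulli with probability
#' `detection_prob x (mean occupancy along the transect)`.
#'
#' @param surface An `occupancy_surface`.
#' @param n_transects Number of transects (> 0).
#' @param length_km Transect length in km.
#' @param detection_prob Detection probability multiplier in `[0, 1]`.
#' @param seed Integer seed.
#' @return A tibble with columns `lon1`, `lat1`, `lon2`, `lat2`, `detected`
#'   and `mean_occupancy` (the generating truth, kept for diagnostics).
#' @export
simulate_transects <- function(surface, n_transects, length_km = 1,
                               detection_prob = 0.6, seed = 1L) {
  stopifnot(n_transects > 0)
  ext <- grid_extent(surface)
  len_deg <- length_km / KM_PER_DEGREE
  if (len_deg >= (ext[["lon_max"]] - ext[["lon_min"]]) ||
      len_deg >= (ext[["lat_max"]] - ext[["lat_min"]])) {
    rlang::abort("transect length exceeds the grid extent",
                 class = "climenvelope_config_error")
  }
  m <- ceiling(sqrt(n_transects))
  withr::with_seed(seed, {
    strata <- sample(rep_len(seq_len(m * m), n_transects))
    sx <- (strata - 1) %% m
    sy <- (strata - 1) %/% m
    w <- (ext[["lon_max"]] - ext[["lon_min"]]) / m
    h <- (ext[["lat_max"]] - ext[["lat_min"]]) / m
    lon1 <- ext[["lon_min"]] + (sx + runif(n_transects)) * w
    lat1 <- ext[["lat_min"]] + (sy + runif(n_transects)) * h
    theta <- runif(n_transects, 0, 2 * pi)
    lon2 <- lon1 + len_deg * cos(theta) / cos(lat1 * pi / 180)
    lat2 <- lat1 + len_deg * sin(theta)
    # mean occupancy along 11 evenly spaced stations
    frac <- seq(0, 1, length.out = 11)
    mean_occ <- vapply(seq_len(n_transects), function(i) {
      mean(occupancy_at(surface,
                        lon1[i] + frac * (lon2[i] - lon1[i]),
                        lat1[i] + frac * (lat2[i] - lat1[i])))
    }, numeric(1))
    detected <- runif(n_transects) < detection_prob * mean_occ
  })
  tibble(lon1 = lon1, lat1 = lat1, lon2 = lon2, lat2 = lat2,
         detected = detected, mean_occupancy = mean_occ)
}

#' Apply additive per-band climate deltas to produce a future grid
#'
#' Future scenario grids are the current grid plus a per-band additive
#' offset (one offset per bioclim band; zero allowed), standing in for the
#' per-GCM bioclim projections. Geometry is unchanged; scenario metadata is
#' recorded on the output.
#'
#' @param current A `climate_grid`.
#' @param deltas Named numeric with one offset per [bioclim_vars()].
#' @param scenario A [scenario_future()] descriptor.
#' @return A `climate_grid` for the scenario.
#' @export
generate_future_grid <- function(current, deltas, scenario) {
  missing <- setdiff(bioclim_vars(), names(deltas))
  if (length(missing)) {
    rlang::abort(paste0("`deltas` missing offset(s) for: ",
                        paste(missing, collapse = ", ")),
                 class = "climenvelope_schema_error")
  }
  data <- as_tibble(current)
  for (b in bioclim_vars()) data[[b]] <- data[[b]] + deltas[[b]]
  new_grid_tbl(data, grid_resolution(current), grid_extent(current),
               scenario, "climate_grid")
}

#' Synthetic GCM delta sets
#'
#' Six labelled synthetic GCM offset sets per RCP and projection year. Mean
#' warming per RCP/year follows the best-estimate global mean surface
#' temperature ranges associated with the four pathways, interpolated to
#' 2050/2070, and is spread across the six GCMs by fixed multipliers; the
#' dry-quarter precipitation offset varies mildly by GCM around zero
#' (warming dominates, precipitation changes little). These are synthetic
#' stand-ins, not any real GCM's output.
#'
#' @param rcps,years Scenario axes to enumerate.
#' @return A tibble with columns `gcm`, `rcp`, `year` and one delta column
#'   per bioclim band (`d_bio_maxtemp`, ...).
#' @export
gcm_delta_table <- function(rcps = c(2.6, 4.5, 6.0, 8.5),
                            years = c(2050L, 2070L)) {
  rcp_levels <- c(2.6, 4.5, 6.0, 8.5)
  base_warming <- c(1.0, 1.4, 1.5, 2.0)
  growth_2070 <- c(1.0, 1.3, 1.5, 1.85)
  gcm_mult <- c(gcm1 = 0.70, gcm2 = 0.85, gcm3 = 1.00,
                gcm4 = 1.10, gcm5 = 1.25, gcm6 = 1.40)
  gcm_pdry <- c(gcm1 = -4, gcm2 = -2, gcm3 = 0, gcm4 = 1, gcm5 = 3, gcm6 = 5)
  stopifnot(all(rcps %in% rcp_levels))
  tidyr::expand_grid(gcm = names(gcm_mult), rcp = rcps, year = years) %>%
    dplyr::mutate(
      warm = base_warming[match(.data$rcp, rcp_levels)] *
        ifelse(.data$year == 2070L,
               growth_2070[match(.data$rcp, rcp_levels)], 1),
      d_bio_maxtemp = .data$warm * gcm_mult[.data$gcm],
      d_bio_tseason = 20 * gcm_mult[.data$gcm],
      d_bio_trange = 0.2 * gcm_mult[.data$gcm],
      d_bio_pwet = -5 * gcm_mult[.data$gcm],
      d_bio_pdry = gcm_pdry[.data$gcm]
    ) %>%
    dplyr::select(-"warm")
}
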