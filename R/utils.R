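#' @importFrom rlang %||% abort warn inform .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats plogis predict rnorm runif setNames quantile
#' @importFrom dplyr %>%
NULL

#' Names of the five bioclimatic covariates
#'
#' The covariate set used throughout the package: maximum temperature of the
#' warmest month (`bio_maxtemp`, degrees C), temperature seasonality
#' (`bio_tseason`, unitless index), annual temperature range (`bio_trange`,
#' degrees C), precipitation of the wettest quarter (`bio_pwet`, mm) and
#' precipitation of the driest quarter (`bio_pdry`, mm).
#'
#' @return Character vector of length five.
#' @export
bioclim_vars <- function() {
  c("bio_maxtemp", "bio_tseason", "bio_trange", "bio_pwet", "bio_pdry")
}

# mean Earth radius used for all great-circle work
EARTH_RADIUS_KM <- 6371
KM_PER_DEGREE <- 111.32

#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6,371 km. Inputs are recycled the
#' usual way, so a single point against a vector of points works.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees.
#' @return Distances in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

# great-circle midpoint via normalised Cartesian mean; on a meridian this
# reduces to the arithmetic mean of the latitudes
geodesic_midpoint <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  x1 <- cos(lat1 * to_rad) * cos(lon1 * to_rad)
  y1 <- cos(lat1 * to_rad) * sin(lon1 * to_rad)
  z1 <- sin(lat1 * to_rad)
  x2 <- cos(lat2 * to_rad) * cos(lon2 * to_rad)
  y2 <- cos(lat2 * to_rad) * sin(lon2 * to_rad)
  z2 <- sin(lat2 * to_rad)
  x <- (x1 + x2) / 2; y <- (y1 + y2) / 2; z <- (z1 + z2) / 2
  hyp <- sqrt(x^2 + y^2)
  tibble(
    lon = atan2(y, x) / to_rad,
    lat = atan2(z, hyp) / to_rad
  )
}

#' Derive a stage-specific seed from a run seed
#'
#' One global seed fans out deterministically to per-stage seeds so that each
#' pipeline stage is independently reproducible. The derivation is a fixed
#' integer hash of the stage name folded into the run seed, kept below 2^31.
#'
#' @param seed Integer run seed.
#' @param stage Character stage label.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 48271 + h * 16807) %% (2^31 - 1))
}

# check a numeric vector is finite, for argument validation
assert_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    abort(sprintf("`%s` contains non-finite values", what), class = "climenvelope_schema_error")
  }
  invisible(x)
}

assert_has_cols <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(
      sprintf("%s is missing required column(s): %s", what,
              paste(missing, collapse = ", ")),
      class = "climenvelope_schema_error"
    )
  }
  invisible(data)
}
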