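# Shared fixtures, memoised so expensive objects are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, .fixture_cache)) {
    assign(name, builder(), .fixture_cache)
  }
  get(name, .fixture_cache)
}

# the default stated world, as used for parameter-recovery checks
default_fixture <- function() {
  memo("default", function() {
    cfg <- synthetic_world_config()
    grid <- generate_climate_grid(cfg)
    occ <- true_occupancy(grid, cfg)
    pres <- sample_presences(occ, cfg$n_presence, 42)
    tr <- simulate_transects(occ, cfg$n_transects, cfg$transect_length_km,
                             cfg$detection_prob, 42)
    ab <- transect_absence_midpoints(tr)
    pa <- sample_pseudo_absences(grid_extent(grid), pres, 4764, 10, 42)
    ft <- suppressMessages(assemble_training_set(pres, ab, pa, grid))
    seg <- radial_segments(ft, 5)
    list(cfg = cfg, grid = grid, occ = occ, pres = pres, tr = tr,
         ft = ft, seg = seg)
  })
}

# a coarse miniature world for cheap structural tests
small_fixture <- function() {
  memo("small", function() {
    # gradients steepened so the 2 x 1.5 degree window still spans both
    # sides of the occupancy thresholds
    cfg <- synthetic_world_config(
      extent = c(lon_min = 37, lon_max = 39, lat_min = 4, lat_max = 5.5),
      resolution = 0.1, core_center = c(lon = 38, lat = 4.75),
      temp_gradient = 8, precip_dry_gradient = 60,
      n_presence = 150, n_transects = 60, seed = 3L)
    grid <- generate_climate_grid(cfg)
    occ <- true_occupancy(grid, cfg)
    pres <- sample_presences(occ, cfg$n_presence, 11)
    pa <- sample_pseudo_absences(grid_extent(grid), pres, 600, 5, 11)
    ft <- suppressMessages(assemble_training_set(
      pres, transect_absence_midpoints(
        simulate_transects(occ, 60, 1, 0.5, 11)), pa, grid))
    list(cfg = cfg, grid = grid, occ = occ, pres = pres, ft = ft)
  })
}

# hand-built grid with arbitrary band values (for exact-arithmetic tests)
manual_grid <- function(values, extent, resolution) {
  cells <- climenvelope:::grid_centres(extent, resolution)
  data <- tibble::as_tibble(c(list(lon = cells$lon, lat = cells$lat), values))
  climenvelope:::new_grid_tbl(data, resolution, extent,
                              scenario_current(), "climate_grid")
}

# a separable feature table: presence iff bio_maxtemp below a cut
separable_table <- function(n = 400, cut = 31, seed = 5) {
  withr::with_seed(seed, {
    maxtemp <- c(runif(n / 2, 27, cut - 0.2), runif(n / 2, cut + 0.2, 40))
    tibble::tibble(
      lon = runif(n, 36, 40), lat = runif(n, 3.5, 6.5),
      label = rep(c("presence", "pseudo_absence"), each = n / 2),
      source = rep(c("sighting", "random_background"), each = n / 2),
      response = rep(1:0, each = n / 2),
      bio_maxtemp = maxtemp,
      bio_tseason = rnorm(n, 1200, 40),
      bio_trange = rnorm(n, 15, 1),
      bio_pwet = rnorm(n, 340, 25),
      bio_pdry = rnorm(n, 60, 10))
  })
}

# brute-force all-pairs AUC oracle
auc_bruteforce <- function(observed, predicted) {
  pos <- predicted[observed == 1]
  neg <- predicted[observed == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# exhaustive-search max-kappa oracle
kappa_at <- function(observed, predicted, t) {
  pred <- as.integer(predicted >= t)
  tp <- sum(pred == 1 & observed == 1); fp <- sum(pred == 1 & observed == 0)
  fn <- sum(pred == 0 & observed == 1); tn <- sum(pred == 0 & observed == 0)
  n <- length(observed)
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  if (abs(1 - pe) < 1e-12) return(0)
  (po - pe) / (1 - pe)
}

max_kappa_bruteforce <- function(observed, predicted) {
  cand <- sort(unique(c(0, predicted, 1)))
  ks <- vapply(cand, function(t) kappa_at(observed, predicted, t), numeric(1))
  best <- which.max(ks)
  list(threshold = cand[best], kappa = ks[best])
}
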