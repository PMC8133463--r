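test_that("climate grid is deterministic and radially structured", {
  cfg <- synthetic_world_config(seed = 9L)
  g1 <- generate_climate_grid(cfg)
  g2 <- generate_climate_grid(cfg)
  expect_identical(g1, g2)

  # noise-free limit: max temperature is the exact radial function
  cfg0 <- synthetic_world_config(
    noise_sd = c(bio_maxtemp = 0, bio_tseason = 0, bio_trange = 0,
                 bio_pwet = 0, bio_pdry = 0), seed = 9L)
  g0 <- generate_climate_grid(cfg0)
  d <- sqrt((g0$lon - cfg0$core_center[["lon"]])^2 +
            (g0$lat - cfg0$core_center[["lat"]])^2)
  expect_equal(g0$bio_maxtemp, cfg0$temp_core + cfg0$temp_gradient * d)
  expect_equal(g0$lon[which.min(g0$bio_maxtemp)],
               cfg0$core_center[["lon"]], tolerance = cfg0$resolution)
  expect_equal(g0$lat[which.min(g0$bio_maxtemp)],
               cfg0$core_center[["lat"]], tolerance = cfg0$resolution)
  # dry-quarter precipitation increases away from the core (its distance
  # field is anisotropic, so correlation with radial distance is imperfect)
  expect_gt(cor(g0$bio_pdry, d), 0.5)
  expect_equal(g0$bio_pdry[which.min(d)], min(g0$bio_pdry) ,
               tolerance = cfg0$precip_dry_gradient * cfg0$resolution * 2)
})

test_that("every band is spatially autocorrelated (lag-1 > 0.5)", {
  g <- default_fixture()$grid
  nx <- length(unique(g$lon))
  for (b in bioclim_vars()) {
    m <- matrix(g[[b]], nrow = nx)  # columns = latitude rows
    lag_e <- cor(as.vector(m[-nx, ]), as.vector(m[-1, ]))
    lag_n <- cor(as.vector(m[, -ncol(m)]), as.vector(m[, -1]))
    expect_gt(lag_e, 0.5)
    expect_gt(lag_n, 0.5)
  }
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_world_config(resolution = 0),
               class = "climenvelope_config_error")
  expect_error(synthetic_world_config(
    extent = c(lon_min = 40, lon_max = 36, lat_min = 3.5, lat_max = 6.5)),
    class = "climenvelope_config_error")
  expect_error(synthetic_world_config(temp_softness = -1),
               class = "climenvelope_config_error")
  expect_error(synthetic_world_config(detection_prob = 0),
               class = "climenvelope_config_error")
})

test_that("true occupancy follows the product-of-logistics form", {
  cfg <- synthetic_world_config(temp_threshold = 33, temp_softness = 1,
                                precip_threshold = 60, precip_softness = 8)
  ext <- c(lon_min = 0, lon_max = 0.2, lat_min = 0, lat_max = 0.05)
  g <- manual_grid(list(
    bio_maxtemp = c(33, 33, 38, 30),
    bio_tseason = rep(1200, 4), bio_trange = rep(15, 4),
    bio_pwet = rep(340, 4),
    bio_pdry = c(-500, 60, -500, -500)), ext, 0.05)
  occ <- true_occupancy(g, cfg)
  expect_equal(occ$occupancy[1], 0.5, tolerance = 1e-12)    # T = T0, P << P0
  expect_equal(occ$occupancy[2], 0.25, tolerance = 1e-12)   # T = T0, P = P0
  expect_equal(occ$occupancy[3], plogis(-5), tolerance = 1e-9)  # T0+5, sT=1
  expect_true(all(occ$occupancy >= 0 & occ$occupancy <= 1))
  expect_error(true_occupancy(g[, c("lon", "lat")], cfg),
               class = "climenvelope_schema_error")
})

test_that("occupancy is non-increasing in temperature and dry precipitation", {
  cfg <- synthetic_world_config()
  ext <- c(lon_min = 0, lon_max = 1, lat_min = 0, lat_max = 0.05)
  tvals <- seq(20, 45, length.out = 20)
  g <- manual_grid(list(bio_maxtemp = tvals, bio_tseason = rep(0, 20),
                        bio_trange = rep(0, 20), bio_pwet = rep(0, 20),
                        bio_pdry = rep(50, 20)), ext, 0.05)
  occ <- true_occupancy(g, cfg)
  expect_true(all(diff(occ$occupancy) <= 0))
  g2 <- manual_grid(list(bio_maxtemp = rep(30, 20), bio_tseason = rep(0, 20),
                         bio_trange = rep(0, 20), bio_pwet = rep(0, 20),
                         bio_pdry = seq(10, 150, length.out = 20)), ext, 0.05)
  occ2 <- true_occupancy(g2, cfg)
  expect_true(all(diff(occ2$occupancy) <= 0))
})

test_that("presence sampling respects support and the occupancy envelope", {
  fx <- default_fixture()
  expect_identical(nrow(sample_presences(fx$occ, 0, 1)), 0L)

  # single-support surface: all points inside that cell
  surf <- fx$occ
  single <- surf
  single$occupancy <- c(1, rep(0, nrow(surf) - 1))
  pts <- sample_presences(single, 50, 4)
  res <- grid_resolution(surf)
  expect_true(all(abs(pts$lon - surf$lon[1]) <= res / 2))
  expect_true(all(abs(pts$lat - surf$lat[1]) <= res / 2))

  zero <- surf; zero$occupancy <- rep(0, nrow(surf))
  expect_error(sample_presences(zero, 5, 1),
               class = "climenvelope_unsampleable_error")

  # sampled points sit on the cool side of the temperature threshold
  pts <- sample_presences(fx$occ, 2000, 8)
  idx <- climenvelope:::cell_index(pts$lon, pts$lat, grid_extent(fx$grid),
                                   grid_resolution(fx$grid))
  tvals <- fx$grid$bio_maxtemp[idx]
  frac <- mean(tvals < fx$cfg$temp_threshold + 2 * fx$cfg$temp_softness)
  expect_gt(frac, 0.95)
  ext <- grid_extent(fx$grid)
  expect_true(all(pts$lon >= ext[["lon_min"]] & pts$lon <= ext[["lon_max"]]))
  expect_true(all(pts$lat >= ext[["lat_min"]] & pts$lat <= ext[["lat_max"]]))
})

test_that("transect simulation matches its detection model", {
  fx <- default_fixture()
  tr0 <- simulate_transects(fx$occ, 100, 1, detection_prob = 0, seed = 2)
  expect_true(all(!tr0$detected))

  ones <- fx$occ; ones$occupancy <- rep(1, nrow(ones))
  tr1 <- simulate_transects(ones, 100, 1, detection_prob = 1, seed = 2)
  expect_true(all(tr1$detected))

  # detected fraction within 3 SE of the truth-derived expectation
  tr <- simulate_transects(fx$occ, 255, 1, 0.6, seed = 21)
  p_i <- 0.6 * tr$mean_occupancy
  se <- sqrt(sum(p_i * (1 - p_i))) / length(p_i)
  expect_lt(abs(mean(tr$detected) - mean(p_i)), 3 * se)

  # transects are about 1 km long
  len <- haversine_km(tr$lon1, tr$lat1, tr$lon2, tr$lat2)
  expect_true(all(abs(len - 1) < 0.2))

  expect_error(simulate_transects(fx$occ, 5, length_km = 1e5),
               class = "climenvelope_config_error")
})

test_that("future grids are additive with scenario metadata", {
  g <- small_fixture()$grid
  zero <- setNames(rep(0, 5), bioclim_vars())
  sc <- scenario_future("gcm1", 4.5, 2050L)
  f0 <- generate_future_grid(g, zero, sc)
  expect_equal(as.data.frame(f0), as.data.frame(g), ignore_attr = TRUE)
  expect_identical(grid_scenario(f0)$gcm, "gcm1")

  plus3 <- zero; plus3[["bio_maxtemp"]] <- 3
  f3 <- generate_future_grid(g, plus3, sc)
  expect_equal(mean(f3$bio_maxtemp) - mean(g$bio_maxtemp), 3, tolerance = 1e-12)

  expect_error(generate_future_grid(g, zero[-1], sc),
               class = "climenvelope_schema_error")

  # across-GCM spread of grid means equals the spread of the offsets
  offs <- c(0.5, 1, 1.5, 2, 2.5, 3)
  means <- vapply(offs, function(o) {
    d <- zero; d[["bio_maxtemp"]] <- o
    mean(generate_future_grid(g, d, sc)$bio_maxtemp)
  }, numeric(1))
  expect_equal(diff(range(means)), diff(range(offs)), tolerance = 1e-10)
})

test_that("grid CSV round trip preserves data and metadata", {
  g <- small_fixture()$grid
  path <- withr::local_tempfile(fileext = ".csv")
  write_grid_csv(g, path)
  g2 <- read_grid_csv(path)
  expect_equal(tibble::as_tibble(g2), tibble::as_tibble(g), tolerance = 1e-9)
  expect_equal(grid_resolution(g2), grid_resolution(g))
  expect_equal(grid_extent(g2), grid_extent(g))
})
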