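test_that("projection agrees with point predictions and recovers truth", {
  fx <- small_fixture()
  m <- fit_sdm(fx$ft, algorithm_spec("GLM"))
  surf <- project_surface(m, fx$grid)
  expect_true(all(surf$probability >= 0 & surf$probability <= 1))

  # grid-cell values match predict() on rows extracted from the same cells
  idx <- climenvelope:::cell_index(fx$ft$lon, fx$ft$lat,
                                   grid_extent(fx$grid),
                                   grid_resolution(fx$grid))
  expect_equal(surf$probability[idx], predict(m, fx$ft), tolerance = 1e-12)

  # fitted surface correlates strongly with the generating occupancy
  expect_gt(cor(surf$probability, fx$occ$occupancy), 0.7)

  expect_error(project_surface(m, fx$grid[, 1:4]),
               class = "climenvelope_schema_error")
})

test_that("missing band values become no-data cells and propagate", {
  fx <- small_fixture()
  m <- fit_sdm(fx$ft, algorithm_spec("GLM"))
  g <- fx$grid
  g$bio_pdry[c(3, 7)] <- NA
  surf <- project_surface(m, g)
  expect_true(all(is.na(surf$probability[c(3, 7)])))
  expect_true(all(!is.na(surf$probability[-c(3, 7)])))
  mask <- binarize(surf, 0.5)
  expect_true(all(is.na(mask$presence[c(3, 7)])))
  # ensemble propagates no-data
  ens <- ensemble_mean_surface(list(surf, surf))
  expect_true(all(is.na(ens$probability[c(3, 7)])))
})

test_that("binarisation is monotone in the threshold", {
  fx <- small_fixture()
  m <- fit_sdm(fx$ft, algorithm_spec("GLM"))
  surf <- project_surface(m, fx$grid)
  m0 <- binarize(surf, 0)
  expect_true(all(m0$presence == 1L))
  expect_error(binarize(surf, 1.0001), class = "climenvelope_config_error")
  m1 <- binarize(surf, 1)
  expect_identical(sum(m1$presence), sum(surf$probability >= 1))
  thresholds <- c(0, 0.2, 0.5, 0.8, 1)
  counts <- vapply(thresholds, function(t) sum(binarize(surf, t)$presence),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("cell areas match spherical geometry", {
  # single 30-arc-second cell centred on the equator
  r <- 1 / 120
  ext <- c(lon_min = 0, lon_max = r, lat_min = -r / 2, lat_max = r / 2)
  surf <- climenvelope:::new_grid_tbl(
    tibble::tibble(lon = r / 2, lat = 0, probability = 1),
    r, ext, scenario_current(), "suitability_surface")
  area <- mask_area_km2(binarize(surf, 0.5))
  # independent spherical-cap oracle: R^2 * dlambda * (sin phi2 - sin phi1)
  R <- 6371
  sph <- R^2 * (r * pi / 180) *
    (sin((r / 2) * pi / 180) - sin((-r / 2) * pi / 180))
  expect_lt(abs(area - sph) / sph, 0.005)

  # empty mask
  surf0 <- surf; surf0$probability <- 0
  expect_identical(mask_area_km2(binarize(surf0, 0.5)), 0)

  # reflection about the equator preserves area
  extN <- c(lon_min = 0, lon_max = 0.5, lat_min = 30, lat_max = 30.5)
  extS <- c(lon_min = 0, lon_max = 0.5, lat_min = -30.5, lat_max = -30)
  mk <- function(ext) {
    cells <- climenvelope:::grid_centres(ext, 0.1)
    climenvelope:::new_grid_tbl(
      tibble::tibble(lon = cells$lon, lat = cells$lat,
                     presence = rep(1L, nrow(cells))),
      0.1, ext, scenario_current(), "range_mask")
  }
  expect_equal(mask_area_km2(mk(extN)), mask_area_km2(mk(extS)),
               tolerance = 1e-12)

  # additivity over disjoint halves
  whole <- mk(extN)
  a <- whole; a$presence[seq_len(nrow(a)) %% 2 == 0L] <- 0L
  b <- whole; b$presence[seq_len(nrow(b)) %% 2 == 1L] <- 0L
  expect_equal(mask_area_km2(a) + mask_area_km2(b), mask_area_km2(whole),
               tolerance = 1e-9)
})

test_that("ensemble means behave like arithmetic means", {
  fx <- small_fixture()
  m <- fit_sdm(fx$ft, algorithm_spec("GLM"))
  surf <- project_surface(m, fx$grid)
  expect_equal(ensemble_mean_surface(list(surf))$probability,
               surf$probability)
  flip <- surf; flip$probability <- 1 - surf$probability
  expect_equal(ensemble_mean_surface(list(surf, flip))$probability,
               rep(0.5, nrow(surf)))
  expect_equal(ensemble_mean_surface(list(surf, surf, surf))$probability,
               surf$probability)
  other <- climenvelope:::new_grid_tbl(
    tibble::tibble(lon = 0, lat = 0, probability = 1), 1,
    c(lon_min = 0, lon_max = 1, lat_min = 0, lat_max = 1),
    scenario_current(), "suitability_surface")
  expect_error(ensemble_mean_surface(list(surf, other)),
               class = "climenvelope_schema_error")
})

test_that("percent_left matches the published worked examples", {
  expect_identical(percent_left(8311, 8311), 100L)
  expect_identical(percent_left(3642, 8311), 44L)
  expect_identical(percent_left(1583, 8311), 19L)
  expect_identical(percent_left(136, 3495), 4L)
  expect_identical(percent_left(5, 3495), 0L)
  expect_error(percent_left(10, 0), class = "climenvelope_degenerate_error")
})

test_that("the scenario range table transfers current thresholds", {
  fx <- small_fixture()
  models <- list(GLM = fit_sdm(fx$ft, algorithm_spec("GLM")),
                 RF = fit_sdm(fx$ft, algorithm_spec("RF", seed = 2,
                                                    n_trees = 60)))
  thresholds <- lapply(models, function(m)
    max_kappa_threshold(fx$ft$response, predict(m, fx$ft)))

  # future identical to current -> percent_left 100 everywhere
  same <- generate_future_grid(fx$grid, setNames(rep(0, 5), bioclim_vars()),
                               scenario_future("gcm1", 2.6, 2050L))
  rt <- scenario_range_table(models, thresholds, list(same), fx$grid)
  expect_identical(rt$percent_left[2], 100L)
  expect_equal(rt$mean_area_km2[2], rt$mean_area_km2[1], tolerance = 1e-9)

  # member bookkeeping: mean within [min, max]
  warm <- generate_future_grid(fx$grid,
                               setNames(c(2, 0, 0, 0, 0), bioclim_vars()),
                               scenario_future("gcm2", 8.5, 2070L))
  rt2 <- scenario_range_table(models, thresholds, list(same, warm), fx$grid)
  fut <- rt2[-1, ]
  expect_true(all(fut$mean_area_km2 >= fut$area_min - 1e-9))
  expect_true(all(fut$mean_area_km2 <= fut$area_max + 1e-9))
  members <- range_table_members(rt2)
  expect_identical(nrow(members), 4L)  # 2 scenarios x 2 algorithms

  # thresholds not matching models are rejected
  expect_error(scenario_range_table(models, thresholds["GLM"], list(same),
                                    fx$grid),
               class = "climenvelope_config_error")
  expect_error(scenario_range_table(models,
                                    list(GLM = 2, RF = thresholds$RF),
                                    list(same), fx$grid),
               class = "climenvelope_config_error")
  # a 'future' grid carrying the current scenario is rejected
  expect_error(scenario_range_table(models, thresholds, list(fx$grid),
                                    fx$grid),
               class = "climenvelope_config_error")
})
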