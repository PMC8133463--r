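test_that("radial segment assignment follows bearings from the centre", {
  expect_error(radial_segments(tibble::tibble(lon = 1, lat = 1), k = 1),
               class = "climenvelope_config_error")
  expect_error(radial_segments(tibble::tibble(lon = numeric(),
                                              lat = numeric()), k = 2),
               class = "climenvelope_config_error")

  ctr <- c(lon = 38, lat = 5)
  ew <- tibble::tibble(lon = c(39, 37), lat = c(5, 5))
  seg2 <- radial_segments(ew, 2, center = ctr)
  expect_identical(length(unique(seg2$segment)), 2L)

  # five points at bearings 10, 80, 150, 220, 290 -> five distinct sectors
  br <- c(10, 80, 150, 220, 290) * pi / 180
  pts <- tibble::tibble(lon = 38 + 0.5 * cos(br), lat = 5 + 0.5 * sin(br))
  seg5 <- radial_segments(pts, 5, center = ctr)
  expect_identical(sort(seg5$segment), 0:4)

  # a record exactly at the centre sits in sector 0
  at_ctr <- radial_segments(tibble::tibble(lon = 38, lat = 5), 3,
                            center = ctr)
  expect_identical(at_ctr$segment, 0L)

  # uniform ring of 1,000 points -> 200 per sector by construction
  th <- (seq_len(1000) - 0.5) * 2 * pi / 1000
  ring <- tibble::tibble(lon = 38 + cos(th), lat = 5 + sin(th))
  segr <- radial_segments(ring, 5, center = ctr)
  expect_identical(unname(tabulate(segr$segment + 1L, 5)), rep(200L, 5))

  # default centre is the presence centroid
  lab <- tibble::tibble(lon = c(0, 10, 20), lat = c(0, 10, 20),
                        label = c("presence", "presence", "pseudo_absence"))
  sd <- radial_segments(lab, 4)
  expect_equal(unname(sd$center), c(5, 5))
})

test_that("auc_roc equals brute-force all-pairs concordance", {
  # worked example: 5 wins, no ties over the 6 presence-absence pairs
  obs <- c(1, 1, 0, 0, 0)
  pred <- c(0.9, 0.4, 0.5, 0.3, 0.3)
  expect_equal(auc_bruteforce(obs, pred), 5 / 6)
  expect_equal(auc_roc(obs, pred), 5 / 6)

  expect_equal(auc_roc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_equal(auc_roc(c(1, 0, 1, 0), rep(0.4, 4)), 0.5)
  expect_error(auc_roc(c(1, 1), c(0.2, 0.3)),
               class = "climenvelope_degenerate_error")

  # property: random instances with heavy ties
  withr::with_seed(14, {
    for (i in 1:40) {
      n <- sample(5:200, 1)
      obs <- c(1, 0, rbinom(n - 2, 1, 0.4))
      pred <- round(runif(n), sample(1:3, 1))
      expect_equal(auc_roc(obs, pred), auc_bruteforce(obs, pred),
                   tolerance = 1e-12)
    }
  })
})

test_that("AUC is invariant under strictly monotone transforms", {
  withr::with_seed(3, {
    obs <- rbinom(300, 1, 0.3)
    pred <- runif(300)
    a <- auc_roc(obs, pred)
    expect_equal(auc_roc(obs, plogis(5 * pred - 2)), a)
    expect_equal(auc_roc(obs, pred^3), a)
    expect_equal(auc_roc(obs, exp(pred)), a)
  })
})

test_that("max_kappa_threshold equals exhaustive search", {
  # worked example
  obs <- c(1, 1, 0, 0)
  pred <- c(0.8, 0.6, 0.7, 0.2)
  got <- max_kappa_threshold(obs, pred)
  want <- max_kappa_bruteforce(obs, pred)
  expect_equal(got$kappa, want$kappa, tolerance = 1e-12)
  expect_equal(got$threshold, want$threshold)

  # perfectly separated: kappa 1 at the smallest separating threshold
  sep <- max_kappa_threshold(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.1))
  expect_equal(sep$kappa, 1.0)
  expect_equal(sep$threshold, 0.8)

  expect_error(max_kappa_threshold(c(1, 1), c(0.5, 0.6)),
               class = "climenvelope_degenerate_error")

  # property: random instances, with ties
  withr::with_seed(15, {
    for (i in 1:40) {
      n <- sample(5:200, 1)
      obs <- c(1, 0, rbinom(n - 2, 1, 0.3))
      pred <- round(runif(n), sample(1:2, 1))
      got <- max_kappa_threshold(obs, pred)
      want <- max_kappa_bruteforce(obs, pred)
      expect_equal(got$kappa, want$kappa, tolerance = 1e-12)
      expect_equal(got$threshold, want$threshold)
    }
  })
})

test_that("leave-one-segment-out predictions cover every record once", {
  fx <- small_fixture()
  seg <- radial_segments(fx$ft, 4)
  cv <- loocv_predict(fx$ft, algorithm_spec("GLM"), seg)
  expect_identical(nrow(cv), nrow(fx$ft))
  expect_true(all(!is.na(cv$prediction)))
  expect_identical(cv$segment, seg$segment)
  gl <- glance(cv)
  expect_equal(gl$auc, attr(cv, "auc"))
  # strong-signal world: spatially blocked AUC is still high
  expect_gt(gl$auc, 0.8)
})

test_that("a single-class fold aborts with the fold named", {
  ft <- separable_table(n = 40)
  # put all presences in one sector: make longitudes encode the class
  ft$lon <- ifelse(ft$response == 1, 39, 37)
  ft$lat <- 5
  seg <- radial_segments(ft, 2, center = c(lon = 38, lat = 5))
  expect_error(loocv_predict(ft, algorithm_spec("GLM"), seg),
               class = "climenvelope_degenerate_fold_error")
})

test_that("delta-AUC importance ranks the governing covariates first", {
  fx <- default_fixture()
  imp <- delta_auc_importance(fx$ft, algorithm_spec("GLM"), fx$seg)
  top2 <- imp$variable[order(-imp$delta_auc)][1:2]
  expect_setequal(top2, c("bio_maxtemp", "bio_pdry"))
  if (all(imp$delta_auc > 0)) {
    expect_equal(sum(imp$share), 1, tolerance = 1e-9)
  } else {
    ok <- !is.na(imp$share)
    if (any(ok)) expect_equal(sum(imp$share[ok]), 1, tolerance = 1e-9)
  }

  # a pure-noise covariate contributes ~zero delta AUC
  ft6 <- fx$ft
  ft6$bio_noise <- withr::with_seed(8, rnorm(nrow(ft6)))
  imp6 <- delta_auc_importance(ft6, algorithm_spec("GLM"), fx$seg,
                               covariates = c(bioclim_vars(), "bio_noise"))
  expect_lt(abs(imp6$delta_auc[imp6$variable == "bio_noise"]), 0.02)
})

test_that("in-sample AUC is an optimistic bound on blocked AUC for trees", {
  fx <- small_fixture()
  seg <- radial_segments(fx$ft, 4)
  diffs <- vapply(1:3, function(s) {
    spec <- algorithm_spec("RF", seed = s, n_trees = 60)
    m <- fit_sdm(fx$ft, spec)
    ins <- auc_roc(fx$ft$response, predict(m, fx$ft))
    cv <- loocv_predict(fx$ft, spec, seg)
    ins - attr(cv, "auc")
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})
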