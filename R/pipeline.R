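# Configuration-driven end-to-end runner: generate -> assemble -> blocked
# cross-validation of all algorithms -> AUC-based selection -> delta-AUC
# importance -> refit on all data -> project all scenarios -> range table.

#' Build a run configuration
#'
#' Defaults mirror the reference workflow: 4,764 pseudo-absences at least
#' 10 km from any presence, five radial cross-validation segments, an AUC
#' selection cutoff of 0.6, all four RCPs and both projection years, six
#' GCM delta sets, and all five algorithms.
#'
#' @param world A [synthetic_world_config()].
#' @param n_pseudo Number of pseudo-absences.
#' @param min_dist_km Pseudo-absence exclusion radius around presences (km).
#' @param k_segments Number of radial cross-validation segments.
#' @param segment_offset Angular offset of the first sector boundary (deg).
#' @param algorithms Character vector of algorithm ids.
#' @param auc_cutoff Pooled LOOCV AUC above which an algorithm advances to
#'   importance analysis and projection.
#' @param rcps,years Scenario axes.
#' @param gcm_deltas Delta table as from [gcm_delta_table()].
#' @param output_dir Optional directory for run artifacts (CSV + manifest);
#'   `NULL` writes nothing.
#' @param seed Integer run seed; fans out to per-stage seeds via
#'   [derive_seed()].
#' @return A validated `run_config` list.
#' @export
run_config <- function(world = synthetic_world_config(),
                       n_pseudo = 4764L, min_dist_km = 10,
                       k_segments = 5L, segment_offset = 0,
                       algorithms = SUPPORTED_ALGORITHMS,
                       auc_cutoff = 0.6,
                       rcps = c(2.6, 4.5, 6.0, 8.5),
                       years = c(2050L, 2070L),
                       gcm_deltas = NULL,
                       output_dir = NULL,
                       seed = 1L) {
  cfg <- list(world = world, n_pseudo = as.integer(n_pseudo),
              min_dist_km = min_dist_km, k_segments = as.integer(k_segments),
              segment_offset = segment_offset,
              algorithms = toupper(algorithms), auc_cutoff = auc_cutoff,
              rcps = rcps, years = as.integer(years),
              gcm_deltas = gcm_deltas %||% gcm_delta_table(rcps, as.integer(years)),
              output_dir = output_dir, seed = as.integer(seed))
  class(cfg) <- "run_config"
  validate_config(cfg)
}

#' Validate and normalise a run configuration
#'
#' Checks every field and reports all violations at once.
#'
#' @param config A `run_config` (or bare list with the same fields).
#' @return The validated `run_config`.
#' @export
validate_config <- function(config) {
  problems <- character()
  if (!inherits(config$world, "synthetic_world_config")) {
    problems <- c(problems, "`world` must be a synthetic_world_config")
  } else {
    world_check <- tryCatch({ validate_world_config(config$world); NULL },
                            error = function(e) conditionMessage(e))
    if (!is.null(world_check)) problems <- c(problems, world_check)
  }
  if (config$n_pseudo < 0) problems <- c(problems, "`n_pseudo` must be >= 0")
  if (config$min_dist_km < 0) problems <- c(problems, "`min_dist_km` must be >= 0")
  if (config$k_segments < 2) problems <- c(problems, "`k_segments` must be >= 2")
  bad_alg <- setdiff(config$algorithms, SUPPORTED_ALGORITHMS)
  if (length(bad_alg)) {
    problems <- c(problems, paste0("unsupported algorithm(s): ",
                                   paste(bad_alg, collapse = ", ")))
  }
  if (config$auc_cutoff < 0 || config$auc_cutoff > 1) {
    problems <- c(problems, "`auc_cutoff` must be in [0, 1]")
  }
  if (length(problems)) {
    rlang::abort(c("invalid run configuration", problems),
                 class = "climenvelope_config_error")
  }
  config
}

#' Read a run configuration from YAML
#'
#' World and run settings are read from a single YAML file; the seed is
#' mandatory. Fields not present fall back to the defaults of
#' [run_config()] / [synthetic_world_config()].
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed)) {
    rlang::abort("config file must set `seed`",
                 class = "climenvelope_config_error")
  }
  world_args <- raw$world %||% list()
  for (f in c("extent", "core_center", "noise_sd")) {
    if (!is.null(world_args[[f]])) world_args[[f]] <- unlist(world_args[[f]])
  }
  if (is.null(world_args$seed)) world_args$seed <- raw$seed
  world <- do.call(synthetic_world_config, world_args)
  run_args <- raw[setdiff(names(raw), "world")]
  run_args$world <- world
  do.call(run_config, run_args)
}

#' Run the full synthetic study
#'
#' Executes the complete pipeline on the synthetic world: climate-grid
#' generation, occupancy and occurrence sampling, transect simulation,
#' pseudo-absence sampling, feature-table assembly, leave-one-segment-out
#' cross-validation of every configured algorithm, AUC-cutoff selection,
#' delta-AUC importance for the selected algorithms, refitting on all data,
#' projection over every GCM x RCP x year scenario, and the range summary
#' table. If `config$output_dir` is set, CSV artifacts and a JSON run
#' manifest are written there.
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage-boundary messages.
#' @return An `sdm_study` list with elements `grid`, `occupancy`,
#'   `presences`, `transects`, `features`, `segments`, `cv` (per-algorithm
#'   evaluations), `auc` (named vector), `selected`, `importance`, `models`,
#'   `thresholds`, `range_table`, `config`.
#' @export
run_synthetic_study <- function(config, quiet = FALSE) {
  config <- validate_config(config)
  say <- function(...) if (!quiet) rlang::inform(sprintf(...))
  seed <- config$seed
  world <- config$world

  grid <- generate_climate_grid(world)
  occupancy <- true_occupancy(grid, world)
  say("generated %d-cell climate grid", nrow(grid))

  presences <- sample_presences(occupancy, world$n_presence,
                                derive_seed(seed, "presences"))
  transects <- simulate_transects(occupancy, world$n_transects,
                                  world$transect_length_km,
                                  world$detection_prob,
                                  derive_seed(seed, "transects"))
  absences <- transect_absence_midpoints(transects)
  say("sampled %d presences; %d/%d transects with detections -> %d absence midpoints",
      nrow(presences), sum(transects$detected), nrow(transects), nrow(absences))

  pseudo <- sample_pseudo_absences(grid_extent(grid), presences,
                                   config$n_pseudo, config$min_dist_km,
                                   derive_seed(seed, "pseudo_absences"))
  features <- assemble_training_set(presences, absences, pseudo, grid)
  say("feature table: %d rows (%d presences, %d zero-response)",
      nrow(features), sum(features$response == 1), sum(features$response == 0))

  segments <- radial_segments(features, config$k_segments,
                              offset = config$segment_offset)

  specs <- lapply(config$algorithms, function(a)
    algorithm_spec(a, seed = derive_seed(seed, paste0("fit_", a))))
  names(specs) <- config$algorithms
  cv <- lapply(specs, function(sp) loocv_predict(features, sp, segments))
  auc <- vapply(cv, function(x) attr(x, "auc"), numeric(1))
  selected <- names(auc)[auc > config$auc_cutoff]
  say("pooled LOOCV AUC: %s; selected (> %.2f): %s",
      paste(sprintf("%s=%.3f", names(auc), auc), collapse = ", "),
      config$auc_cutoff,
      if (length(selected)) paste(selected, collapse = ", ") else "none")
  if (!length(selected)) {
    rlang::abort("no algorithm exceeded the AUC cutoff",
                 class = "climenvelope_degenerate_error")
  }

  importance <- lapply(selected, function(a)
    delta_auc_importance(features, specs[[a]], segments))
  names(importance) <- selected

  models <- lapply(selected, function(a) fit_sdm(features, specs[[a]]))
  names(models) <- selected
  thresholds <- lapply(models, function(m)
    max_kappa_threshold(features$response, predict(m, features)))

  future_grids <- purrr::map(seq_len(nrow(config$gcm_deltas)), function(i) {
    row <- config$gcm_deltas[i, ]
    deltas <- setNames(as.numeric(row[paste0("d_", bioclim_vars())]),
                       bioclim_vars())
    generate_future_grid(grid, deltas,
                         scenario_future(row$gcm, row$rcp, row$year))
  })

  range_table <- if (length(future_grids)) {
    scenario_range_table(models, thresholds, future_grids, grid)
  } else {
    scenario_range_table(models, thresholds, list(), grid)
  }
  say("range table: current mean %.0f km2 over %d algorithm(s), %d scenario row(s)",
      range_table$mean_area_km2[1], length(selected), nrow(range_table) - 1L)

  study <- structure(list(
    grid = grid, occupancy = occupancy, presences = presences,
    transects = transects, features = features, segments = segments,
    cv = cv, auc = auc, selected = selected, importance = importance,
    models = models, thresholds = thresholds, range_table = range_table,
    config = config), class = "sdm_study")

  if (!is.null(config$output_dir)) write_study_artifacts(study, config$output_dir)
  study
}

# deterministic fingerprint of the configuration for the run manifest
config_hash <- function(config) {
  s <- jsonlite::toJSON(config[setdiff(names(config), "output_dir")],
                        auto_unbox = TRUE, digits = NA, force = TRUE)
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 251 + 1)) %% 4294967296)
}

write_study_artifacts <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- study$config
  write_points_csv(dplyr::mutate(study$presences, label = "presence",
                                 source = "sighting"),
                   file.path(dir, "presences.csv"))
  readr::write_csv(study$transects, file.path(dir, "transects.csv"))
  readr::write_csv(study$features, file.path(dir, "features.csv"))
  write_grid_csv(study$grid, file.path(dir, "climate_current.csv"))
  cv_all <- purrr::imap_dfr(study$cv, function(x, a)
    dplyr::mutate(as_tibble(x), algorithm = a))
  readr::write_csv(cv_all, file.path(dir, "cv_predictions.csv"))
  imp_all <- purrr::imap_dfr(study$importance, function(x, a)
    dplyr::mutate(as_tibble(x), algorithm = a))
  readr::write_csv(imp_all, file.path(dir, "importance.csv"))
  thr <- tibble(algorithm = names(study$thresholds),
                threshold = vapply(study$thresholds, `[[`, numeric(1), "threshold"),
                kappa = vapply(study$thresholds, `[[`, numeric(1), "kappa"))
  readr::write_csv(thr, file.path(dir, "thresholds.csv"))
  readr::write_csv(as_tibble(study$range_table), file.path(dir, "range_table.csv"))
  readr::write_csv(range_table_members(study$range_table),
                   file.path(dir, "range_members.csv"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("climenvelope")),
    r_version = as.character(getRversion()),
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    auc = as.list(study$auc),
    selected = study$selected,
    n_features = nrow(study$features))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @exportS3Method base::print
print.sdm_study <- function(x, ...) {
  cat("<sdm_study>\n")
  cat(sprintf("  features: %d rows (%d presences)\n",
              nrow(x$features), sum(x$features$response == 1)))
  cat(sprintf("  LOOCV AUC: %s\n",
              paste(sprintf("%s=%.3f", names(x$auc), x$auc), collapse = ", ")))
  cat(sprintf("  selected: %s\n", paste(x$selected, collapse = ", ")))
  cat(sprintf("  range table: %d scenario rows, current mean %.0f km2\n",
              nrow(x$range_table) - 1L, x$range_table$mean_area_km2[1]))
  invisible(x)
}
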