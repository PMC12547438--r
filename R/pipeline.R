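#' Pipeline configuration
#'
#' Declarative configuration for a full run: data sources (file paths, or
#' synthetic generation when paths are `NULL`), boosting parameters,
#' selection settings, classification thresholds and the master seed.
#' Defaults mirror the survey analysis where stated (ntrees = 400,
#' depth = 1, minobs = 10, 100 replicates, untransformed response).
#'
#' @param stations_path,grid_path,layers_path input files (CSV, CSV,
#'   GeoJSON); any `NULL` entry is generated synthetically.
#' @param params a [boost_params()].
#' @param reps replicate count for LOOMAE and permutation importance.
#' @param log_transform fit on `log1p(response)`? Off by default.
#' @param tune_grid optional list of [boost_params()] to tune over before
#'   selection (`NULL` skips tuning).
#' @param thresholds abundance band edges (upper bounds of low, moderately
#'   elevated, elevated).
#' @param synthetic list of arguments for the synthetic stage: `n`,
#'   `cluster_count`, `nx`, `ny`, `layer_kinds`, `polygons_per_kind`,
#'   `spec` (a [true_model_spec()]).
#' @param seed master seed; every stage derives its own seeds from it.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(stations_path = NULL, grid_path = NULL,
                            layers_path = NULL, params = boost_params(),
                            reps = 100, log_transform = FALSE,
                            tune_grid = NULL,
                            thresholds = c(1000, 2000, 3000),
                            synthetic = list(), seed = 1) {
  if (reps < 1) stop("reps must be >= 1")
  stopifnot(inherits(params, "boost_params"))
  if (!identical(as.numeric(thresholds), c(1000, 2000, 3000)))
    message("pipeline_config: non-default abundance thresholds supplied")
  syn_defaults <- list(n = 56, cluster_count = 5, nx = 20, ny = 20,
                       layer_kinds = c(MPA = "receptor",
                                       disposal_sites = "source",
                                       wind_farms = "source"),
                       polygons_per_kind = 6, spec = default_true_model())
  synthetic <- utils::modifyList(syn_defaults, synthetic)
  structure(list(stations_path = stations_path, grid_path = grid_path,
                 layers_path = layers_path, params = params, reps = reps,
                 log_transform = log_transform, tune_grid = tune_grid,
                 thresholds = as.numeric(thresholds), synthetic = synthetic,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized top-level keys: `stations_path`, `grid_path`, `layers_path`,
#' `params` (ntrees, depth, minobs, shrinkage, bag_fraction), `reps`,
#' `log_transform`, `thresholds`, `synthetic` (n, cluster_count, nx, ny,
#' polygons_per_kind), `seed`. Missing keys fall back to the defaults of
#' [pipeline_config()] (a message notes each block that was defaulted).
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$params)) {
    message("config: no params block, using defaults")
    params <- boost_params()
  } else {
    pd <- utils::modifyList(list(ntrees = 400L, depth = 1L, minobs = 10L,
                                 shrinkage = 0.1, bag_fraction = 0.5,
                                 seed = 1L), cfg$params)
    params <- boost_params(pd$ntrees, pd$depth, pd$minobs, pd$shrinkage,
                           pd$bag_fraction, pd$seed)
  }
  if (is.null(cfg$thresholds))
    message("config: no thresholds block, using 1000/2000/3000")
  pipeline_config(
    stations_path = cfg$stations_path, grid_path = cfg$grid_path,
    layers_path = cfg$layers_path, params = params,
    reps = if (is.null(cfg$reps)) 100 else cfg$reps,
    log_transform = isTRUE(cfg$log_transform),
    thresholds = if (is.null(cfg$thresholds)) c(1000, 2000, 3000)
                 else as.numeric(cfg$thresholds),
    synthetic = if (is.null(cfg$synthetic)) list() else cfg$synthetic,
    seed = if (is.null(cfg$seed)) 1L else cfg$seed
  )
}

# FNV-1a hash of a string, returned as 8 hex digits; used to stamp run
# artifacts with a config fingerprint. 32-bit arithmetic is emulated in
# doubles (the 2^16-split multiply keeps every product below 2^53).
fnv1a_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * m + ((hi * m) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

config_fingerprint <- function(config) {
  ser <- jsonlite::toJSON(list(
    paths = list(config$stations_path, config$grid_path, config$layers_path),
    params = unclass(config$params), reps = config$reps,
    log_transform = config$log_transform, thresholds = config$thresholds,
    synthetic = config$synthetic[c("n", "cluster_count", "nx", "ny",
                                   "polygons_per_kind")],
    seed = config$seed
  ), auto_unbox = TRUE, digits = NA)
  fnv1a_hash(as.character(ser))
}

#' Run the full storage-potential pipeline
#'
#' Executes: data load (or synthetic generation) -> optional parameter
#' tuning -> permutation importance -> forward-selection LOOMAE curve ->
#' best-model choice -> refit on the selected subset -> LOO diagnostics ->
#' residual semivariogram -> grid projection -> layer overlays. All
#' machine-readable artifacts (CSV/JSON/GeoJSON) are deterministic given the
#' config and master seed; stage timings go to `run_log.txt` only.
#'
#' @param config a [pipeline_config()].
#' @param output_dir directory for run artifacts (created if needed).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the in-memory artifacts (`stations`,
#'   `importance`, `curve`, `best`, `model`, `loo`, `semivariogram`,
#'   `surface`, `summaries`, `manifest`).
#' @export
run_pipeline <- function(config, output_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  t0 <- Sys.time()
  say <- function(stage, ...) {
    msg <- paste0("[", stage, "] ", paste0(..., collapse = ""))
    if (!quiet) message(msg)
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%OS2"), " ", msg))
  }
  stage <- function(name, expr) {
    t <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    say(name, "done in ", sprintf("%.2fs", as.numeric(Sys.time() - t,
                                                      units = "secs")))
    res
  }
  seed <- config$seed

  # --- data ----------------------------------------------------------------
  stations <- stage("data", {
    if (!is.null(config$stations_path)) {
      read_station_csv(config$stations_path)
    } else {
      generate_station_dataset(n = config$synthetic$n,
                               spec = config$synthetic$spec,
                               cluster_count = config$synthetic$cluster_count,
                               seed = derive_seed(seed, 1L))$stations
    }
  })
  predictors <- guess_predictors(stations)
  say("data", nrow(stations), " stations, ", length(predictors),
      " candidate predictors")
  write_station_csv(stations, file.path(output_dir, "stations.csv"))

  grid <- stage("grid", {
    if (!is.null(config$grid_path)) read_grid_csv(config$grid_path)
    else generate_prediction_grid(nx = config$synthetic$nx,
                                  ny = config$synthetic$ny,
                                  predictor_names = predictors,
                                  seed = derive_seed(seed, 2L))
  })
  layers <- stage("layers", {
    if (!is.null(config$layers_path)) read_layers_geojson(config$layers_path)
    else generate_risk_layers(config$synthetic$layer_kinds,
                              config$synthetic$polygons_per_kind,
                              seed = derive_seed(seed, 3L))
  })

  # --- parameters ----------------------------------------------------------
  params <- config$params
  params$seed <- derive_seed(seed, 4L)
  if (!is.null(config$tune_grid)) {
    params <- stage("tune", {
      g <- lapply(seq_along(config$tune_grid), function(i) {
        p <- config$tune_grid[[i]]
        p$seed <- derive_seed(seed, 4L, i)
        p
      })
      tune_parameters(stations, predictors, g, config$reps,
                      log_transform = config$log_transform)
    })
    say("tune", "selected grid entry ", attr(params, "grid_index"))
  }

  # --- selection -----------------------------------------------------------
  importance <- stage("importance",
    permutation_importance(stations, predictors, params, config$reps,
                           log_transform = config$log_transform))
  write_csv_exact(as.data.frame(importance),
                  file.path(output_dir, "importance.csv"))
  curve <- stage("selection",
    selection_curve(stations, predictors, params, config$reps,
                    log_transform = config$log_transform,
                    importance = importance))
  best <- select_best_model(curve)
  say("selection", "best model: ", paste(best, collapse = ", "))
  write_selection_report(curve, best, params,
                         file.path(output_dir, "selection.csv"),
                         file.path(output_dir, "selection.json"))

  # --- best model + diagnostics -------------------------------------------
  params_best <- params
  params_best$seed <- derive_seed(seed, 5L)
  model <- stage("fit",
    fit_boosted_model(stations, "mp_count", best, params_best))
  write_model_json(model, file.path(output_dir, "model.json"))

  loo <- stage("loo",
    loo_predictions(stations, best, params_best,
                    log_transform = config$log_transform))
  write_csv_exact(data.frame(station_id = stations$station_id,
                             observed = stations$mp_count,
                             loo_prediction = loo$per_case_prediction,
                             abs_error = loo$abs_error),
                  file.path(output_dir, "loo.csv"))
  say("loo", "LOOMAE = ", sprintf("%.1f", loo$loomae))

  semiv <- stage("semivariogram", {
    resid <- model_residuals(model, stations)
    semivariogram_envelope(stations[, c("lon", "lat")], resid,
                           n_bins = 8, seed = derive_seed(seed, 6L))
  })
  write_csv_exact(as.data.frame(semiv),
                  file.path(output_dir, "semivariogram.csv"))

  # --- projection + overlay ------------------------------------------------
  surface <- stage("surface", predict_surface(model, grid))
  write_grid_csv(surface, file.path(output_dir, "surface.csv"))
  write_surface_geojson(surface, file.path(output_dir, "surface.geojson"))
  write_layers_geojson(layers, file.path(output_dir, "layers.geojson"))

  summaries <- stage("overlay", lapply(layers, function(ly) {
    s <- summarize_layer(surface, ly, config$thresholds)
    write_layer_summary(s,
      file.path(output_dir, paste0("summary_", ly$name, ".csv")),
      file.path(output_dir, paste0("summary_", ly$name, ".json")))
    s
  }))

  manifest <- list(config_hash = config_fingerprint(config),
                   master_seed = seed,
                   n_stations = nrow(stations),
                   candidate_predictors = predictors,
                   selected_predictors = best,
                   loomae_best = loo$loomae,
                   reps = config$reps,
                   artifacts = sort(list.files(output_dir)))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done", "total ", sprintf("%.2fs", as.numeric(Sys.time() - t0,
                                                    units = "secs")))
  writeLines(log_lines, file.path(output_dir, "run_log.txt"))
  invisible(list(stations = stations, grid = grid, layers = layers,
                 params = params, importance = importance, curve = curve,
                 best = best, model = model, loo = loo,
                 semivariogram = semiv, surface = surface,
                 summaries = summaries, manifest = manifest))
}
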