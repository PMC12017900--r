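# Config-driven orchestration of the full framework with stage caching and a
# JSON run manifest.

#' Default run configuration
#'
#' Encodes the framework defaults so deviations are explicit in the config:
#' 500 m reef buffer, 15 m thinning grid, 10,000 biased background points
#' (500 m kernel bandwidth, 0.05 density floor), the 4 x 4 FC-RM candidate
#' grid, 10 evaluation iterations with triplicate background splits, and the
#' `auc_only > 0.7` top-variable rule. Paths are `NULL` placeholders; with
#' `synthetic: true` the input stage generates fixtures instead.
#'
#' @return nested named list of configuration defaults.
#' @export
default_config <- function() {
  list(
    synthetic = TRUE,
    synthetic_spec = list(n_reefs = 3, n_cells = 256, seed = 7),
    paths = list(aca = NULL, dr30 = NULL, dr100 = NULL, records = NULL,
                 tides = NULL, reefs = NULL, out = "reefscape_out"),
    raster = list(aca_divisor = -100, buffer_m = 500, pyramid_cap_m = 120),
    terrain = list(fit_window = 3, vrm_window = 3, bpi_inner_r = 1,
                   bpi_outer_r = 3, svf_azimuths = 16, svf_radius = 10),
    background = list(n = 10000, bandwidth_m = 500, epsilon = 0.05),
    model = list(fc_grid = c("L", "LQ", "LP", "LQP"), rm_grid = c(1, 2, 5, 10),
                 n_iterations = 10, tune_iterations = 1,
                 jackknife_replicates = 3, auc_only_threshold = 0.7),
    response = list(coefficients = c(SLOPE = 5, BPI = 5), intercept = 0,
                    n_presence = 250),
    seed = 1)
}

#' Validate a run configuration
#'
#' Returns a data.frame of issues (empty when the config is valid); rows are
#' labelled `"error"` or `"warning"`.
#'
#' @param config configuration list (see [default_config()]).
#' @return data.frame with columns `level` and `message`.
#' @export
validate_config <- function(config) {
  issues <- list()
  add <- function(level, msg) issues[[length(issues) + 1]] <<-
    data.frame(level = level, message = msg, stringsAsFactors = FALSE)
  m <- config$model
  if (length(m$fc_grid) == 0 || length(m$rm_grid) == 0)
    add("error", "fc/rm candidate grid must be non-empty")
  if (any(!m$fc_grid %in% fc_levels))
    add("error", paste("unknown feature class:",
                       paste(setdiff(m$fc_grid, fc_levels), collapse = ", ")))
  if (any(m$rm_grid <= 0)) add("error", "regularisation multipliers must be > 0")
  tr <- config$terrain
  if (tr$bpi_inner_r >= tr$bpi_outer_r)
    add("error", "bpi_inner_r must be < bpi_outer_r")
  if (tr$fit_window %% 2 != 1 || tr$fit_window < 3)
    add("error", "fit_window must be odd and >= 3")
  if (config$background$n < 1) add("error", "background n must be >= 1")
  if (config$raster$buffer_m < 0) add("error", "buffer_m must be >= 0")
  if (!isTRUE(config$synthetic)) {
    for (p in c("aca", "dr30", "dr100", "reefs")) {
      if (is.null(config$paths[[p]]))
        add("error", paste("path required when synthetic is false:", p))
      else if (!file.exists(config$paths[[p]]))
        add("error", paste("missing input file:", config$paths[[p]]))
    }
  }
  if (config$model$n_iterations < 1) add("error", "n_iterations must be >= 1")
  if (length(issues) == 0)
    data.frame(level = character(0), message = character(0))
  else do.call(rbind, issues)
}

#' Read a YAML run configuration
#'
#' Reads a YAML file and fills unspecified entries from [default_config()].
#'
#' @param path YAML file path.
#' @return configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_cfg <- function(def, usr) {
    # YAML 1.1 parses a bare `n:` key as boolean FALSE; map it back
    names(usr)[names(usr) %in% c("FALSE", "no") & "n" %in% names(def)] <- "n"
    for (k in names(usr)) {
      def[[k]] <- if (is.list(def[[k]]) && is.list(usr[[k]]))
        merge_cfg(def[[k]], usr[[k]]) else usr[[k]]
    }
    def
  }
  merge_cfg(default_config(), user)
}

stage_hash <- function(...) digest::digest(list(...), algo = "md5")

run_stage <- function(name, hash, out_dir, manifest, compute) {
  stamp_file <- file.path(out_dir, "stages", paste0(name, ".json"))
  cached <- FALSE
  if (file.exists(stamp_file)) {
    old <- jsonlite::read_json(stamp_file, simplifyVector = TRUE)
    cached <- identical(old$hash, hash)
  }
  t0 <- proc.time()[["elapsed"]]
  res <- compute()
  dir.create(dirname(stamp_file), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(stage = name, hash = hash, cached = cached,
                            elapsed_s = round(proc.time()[["elapsed"]] - t0, 2)),
                       stamp_file, auto_unbox = TRUE)
  message(sprintf("[reefscape] stage %-12s %s (%.1fs)", name,
                  if (cached) "cached-inputs" else "computed",
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full framework
#'
#' Executes the pipeline end to end: DEM acquisition (synthetic generation or
#' file ingest), Gaussian-pyramid generalisation, terrain derivation,
#' vertical-accuracy assessment, occurrence thinning and biased background
#' sampling, FC-RM tuning by rank sum, the final model with jackknife
#' importance, and a prediction map. Artifacts (CSV/ASCII-grid/JSON) are
#' written under `config$paths$out` and listed in a JSON manifest.
#'
#' @param config configuration list (see [default_config()], [read_config()]).
#' @return the manifest, invisibly (also written to `manifest.json`).
#' @export
run_all <- function(config = default_config()) {
  issues <- validate_config(config)
  if (any(issues$level == "error"))
    stop("invalid config:\n  ", paste(issues$message[issues$level == "error"],
                                      collapse = "\n  "))
  out_dir <- config$paths$out
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()
  seed <- config$seed

  # --- inputs ---------------------------------------------------------------
  world <- run_stage("inputs", stage_hash(config$synthetic, config$synthetic_spec,
                                          config$paths, seed),
                     out_dir, NULL, function() {
    if (isTRUE(config$synthetic)) {
      sp <- do.call(reef_spec, modifyList(list(seed = seed),
                                          config$synthetic_spec))
      generate_reef_dem(sp)
    } else {
      list(aca15 = read_raster(config$paths$aca),
           dr30 = read_raster(config$paths$dr30),
           dr100 = read_raster(config$paths$dr100),
           reefs = read_reefs_geojson(config$paths$reefs), truth = NULL)
    }
  })

  # --- pyramid --------------------------------------------------------------
  stack <- run_stage("pyramid", stage_hash("pyramid", seed), out_dir, NULL,
                     function() build_dem_set(world$aca15, world$dr30, world$dr100))

  # --- terrain --------------------------------------------------------------
  params <- do.call(terrain_params, config$terrain)
  vstack <- run_stage("terrain", stage_hash("terrain", config$terrain), out_dir,
                      NULL, function() derive_all(stack, params))

  # --- occurrences ----------------------------------------------------------
  sim <- run_stage("occurrences", stage_hash("occ", config$response, seed),
                   out_dir, NULL, function() {
    rs <- response_spec(
      coefficients = resolve_response_keys(config$response$coefficients, vstack),
      intercept = config$response$intercept,
      n_presence = config$response$n_presence)
    simulate_occurrences(vstack, rs, world$reefs, seed = seed)
  })

  # --- vertical accuracy ----------------------------------------------------
  accuracy <- run_stage("accuracy", stage_hash("acc", seed), out_dir, NULL,
                        function() {
    rec <- correct_to_lat(sim$depth_records, sim$tides, sim$stations)
    accuracy_by_level(rec, stack)
  })
  write.csv(accuracy, file.path(out_dir, "accuracy.csv"), row.names = FALSE)
  artifacts$accuracy <- "accuracy.csv"

  # --- feature table --------------------------------------------------------
  fine_dem <- stack$levels[[1]]
  thin <- thin_occurrences(sim$presences, fine_dem)
  reef_grids <- crop_to_reefs(fine_dem, world$reefs, config$raster$buffer_m)
  bg <- sample_background(sim$all_coords, reef_grids,
                          n = config$background$n,
                          bias_bandwidth_m = config$background$bandwidth_m,
                          seed = seed, eps = config$background$epsilon)
  table <- build_feature_table(thin, bg, vstack)
  write.csv(table, file.path(out_dir, "feature_table.csv"), row.names = FALSE)
  artifacts$feature_table <- "feature_table.csv"

  # --- tuning ---------------------------------------------------------------
  base_cols <- setdiff(names(table), c("point_id", "reef_id", "label"))
  tune <- run_stage("tune", stage_hash("tune", config$model, seed), out_dir,
                    NULL, function()
    tune_maxent(table, base_cols, fc_grid = config$model$fc_grid,
                rm_grid = config$model$rm_grid,
                n_iterations = config$model$tune_iterations, seed = seed))
  write.csv(tune$selection, file.path(out_dir, "selection.csv"), row.names = FALSE)
  artifacts$selection <- "selection.csv"
  win <- tune$selection[tune$selection$winner, ]

  # --- final model + jackknife ---------------------------------------------
  spec <- feature_spec(win$fc, base_cols)
  X <- expand_features(table, spec)
  final <- fit_maxent(X, table$label, win$rm, spec = spec, seed = seed)
  jk <- jackknife(table, spec, win$rm, seed = seed,
                  n_replicates = config$model$jackknife_replicates)
  write.csv(jk, file.path(out_dir, "jackknife.csv"), row.names = FALSE)
  artifacts$jackknife <- "jackknife.csv"
  save_model(final, file.path(out_dir, "model.json"))
  artifacts$model <- "model.json"

  # --- prediction map -------------------------------------------------------
  pred <- predict(final, vstack)
  write_raster(pred, file.path(out_dir, "prediction.asc"))
  artifacts$prediction <- "prediction.asc"

  manifest <- list(
    package_version = as.character(utils::packageVersion("reefscape")),
    seed = seed,
    config = config,
    n_dem_levels = length(stack),
    n_variable_layers = length(vstack),
    n_presences_thinned = nrow(thin),
    n_background = nrow(bg),
    winner = list(fc = win$fc, rm = win$rm),
    artifacts = artifacts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# map short response keys (e.g. "SLOPE") onto the finest matching layer key
resolve_response_keys <- function(coefs, vstack) {
  keys <- names(vstack$layers)
  out <- numeric(0)
  for (nm in names(coefs)) {
    if (nm %in% keys) { out[nm] <- coefs[[nm]]; next }
    cand <- vstack$key[vstack$key$variable == nm, ]
    if (nrow(cand) == 0) stop("response variable not in stack: ", nm)
    k <- cand$key[which.min(cand$resolution_m)]
    out[k] <- coefs[[nm]]
  }
  out
}

#' Serialise a fitted model to JSON
#'
#' @param model a `maxent_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  obj <- list(fc = model$spec$fc, base_columns = model$spec$base_columns,
              rm = model$rm, intercept = model$intercept,
              coefficients = as.list(model$coefficients),
              scaling = model$scaling, classes = model$classes,
              meta = model$meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model serialised with [save_model()]
#'
#' @param path JSON path.
#' @return a `maxent_model`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    spec = feature_spec(obj$fc, obj$base_columns), rm = obj$rm,
    coefficients = unlist(obj$coefficients), intercept = obj$intercept,
    scaling = lapply(obj$scaling, as.numeric), classes = obj$classes,
    penalties = NULL, zero_variance = character(0), meta = obj$meta),
    class = "maxent_model")
}
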