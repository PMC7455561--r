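#' Derive a per-stage seed from the global run seed
#'
#' One global seed deterministically yields an independent seed per named
#' stage (stage-name hashing), so individual stages can be rerun in
#' isolation with the same stream they had inside the full run.
#'
#' @param seed Global integer seed.
#' @param stage Stage name, e.g. `"thin:wild_goat"`.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 1000003
  as.integer((as.numeric(seed) %% 1000003) * 1009 + h * 31 + 1) %% 2147483646L + 1L
}

default_algorithms <- c("glm", "gam", "gbm", "maxent", "rf")

#' Assemble a pipeline run configuration
#'
#' @param occurrences Named list: species label -> occurrence CSV path.
#' @param rasters Named list: predictor name -> ASCII-grid raster path.
#' @param out_dir Output directory (created; stages append, never
#'   overwrite previous stages' files).
#' @param seed Global integer seed (mandatory).
#' @param elevation Optional path to an elevation raster; when given,
#'   slope and topographic heterogeneity (`th_block` fine cells per coarse
#'   cell) are derived and added to the stack.
#' @param crs CRS kind shared by rasters and occurrences.
#' @param coord_cols Names of the coordinate columns in occurrence files.
#' @param thin_dist Spatial thinning distance in metres (default 5000).
#' @param thin_repeats Randomized thinning repeats (default 100).
#' @param vif_threshold Stepwise-VIF removal threshold (default 10).
#' @param algorithms Algorithms to fit (default all five).
#' @param model_params Named list of per-algorithm hyperparameter lists.
#' @param train_fraction Train split fraction (default 0.8).
#' @param background_n Background sample size (default 10000, capped at
#'   the number of valid cells).
#' @param ensemble_rule `"uniform"` or `"tss"` member weighting.
#' @param th_block Block size for topographic heterogeneity (default 11).
#' @param overlap Compute the pairwise overlap matrix when more than one
#'   species is configured.
#' @return A `run_config` list.
#' @export
run_config <- function(occurrences, rasters, out_dir, seed,
                       elevation = NULL,
                       crs = c("projected", "geographic"),
                       coord_cols = NULL,
                       thin_dist = 5000, thin_repeats = 100,
                       vif_threshold = 10,
                       algorithms = default_algorithms,
                       model_params = list(),
                       train_fraction = 0.8, background_n = 10000,
                       ensemble_rule = c("uniform", "tss"),
                       th_block = 11, overlap = TRUE) {
  crs <- match.arg(crs)
  ensemble_rule <- match.arg(ensemble_rule)
  if (missing(seed) || is.null(seed)) stop("a global `seed` is mandatory")
  if (is.null(coord_cols))
    coord_cols <- if (crs == "geographic") c("lon", "lat") else c("x", "y")
  algorithms <- match.arg(algorithms, default_algorithms,
                          several.ok = TRUE)
  structure(list(
    occurrences = occurrences, rasters = rasters, elevation = elevation,
    out_dir = out_dir, seed = as.integer(seed), crs = crs,
    coord_cols = coord_cols, thin_dist = thin_dist,
    thin_repeats = thin_repeats, vif_threshold = vif_threshold,
    algorithms = algorithms, model_params = model_params,
    train_fraction = train_fraction, background_n = background_n,
    ensemble_rule = ensemble_rule, th_block = th_block,
    overlap = overlap), class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file holds the same flat keys as [run_config()].
#'
#' @param path Path to a YAML config.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(run_config)))]
  do.call(run_config, args)
}

#' Run the full distribution-modelling and overlap pipeline
#'
#' Executes, per species: ingest -> deduplicate -> thin -> (derive terrain
#' predictors) -> align -> VIF selection -> background sampling -> 80/20
#' split -> per-algorithm fits -> per-algorithm evaluation -> ensemble ->
#' ensemble evaluation -> response curves (GLM) -> permutation importance
#' -> binarization at the ensemble's max-TSS threshold with suitable-area
#' estimation; then, across species, the pairwise niche-overlap matrix.
#' All artefacts (CSV, ASCII grids, JSON) land under the configured output
#' directory, and a manifest records per-stage record counts, output paths
#' and timings. The run is fully reproducible from config + seed.
#'
#' @param config A `run_config`, or the path to a YAML config file.
#' @return The run manifest (list), invisibly written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = config[setdiff(names(config), "model_params")],
                   stages = list(), outputs = character(0))
  t_all <- proc.time()[["elapsed"]]
  log_stage <- function(name, info, t0) {
    info$seconds <- round(proc.time()[["elapsed"]] - t0, 2)
    manifest$stages[[name]] <<- info
    message(sprintf("[%s] %s", name,
                    paste(names(info), unlist(info), sep = "=",
                          collapse = " ")))
  }
  add_output <- function(path) {
    manifest$outputs <<- c(manifest$outputs, path)
    path
  }

  # --- predictor stack -----------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  layers <- lapply(config$rasters, read_ascii_grid, crs = config$crs)
  if (!is.null(config$elevation)) {
    elev <- read_ascii_grid(config$elevation, crs = config$crs)
    layers$slope <- compute_slope(elev)
    layers$TH <- compute_topographic_heterogeneity(elev, config$th_block)
  }
  stack <- align_stack(layers)
  log_stage("stack", list(layers = length(stack),
                          valid_cells = length(valid_cells(stack))), t0)

  # --- VIF predictor selection --------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  bg_all <- sample_background(stack, min(config$background_n,
                                         length(valid_cells(stack))),
                              seed = derive_seed(config$seed, "vif"))
  vif_tab <- extract_env_values(bg_all, stack)
  vr <- vif_stepwise(vif_tab, threshold = config$vif_threshold)
  add_output(write_vif_report(vr, file.path(config$out_dir, "vif.json")))
  stack <- predictor_stack(stack[names(vr$vif)])
  log_stage("vif", list(retained = paste(names(vr$vif), collapse = "+"),
                        removed = if (length(vr$removed))
                          paste(vr$removed, collapse = "+") else "none"), t0)

  # --- per-species modelling ----------------------------------------------
  species_results <- list()
  ens_maps <- list()
  for (sp in names(config$occurrences)) {
    res <- model_one_species(sp, config, stack, manifest_log = log_stage,
                             add_output = add_output)
    species_results[[sp]] <- res$summary
    ens_maps[[sp]] <- res$ensemble_map
  }
  manifest$species <- species_results

  # --- niche overlap -------------------------------------------------------
  if (config$overlap && length(ens_maps) > 1) {
    t0 <- proc.time()[["elapsed"]]
    ov <- overlap_matrix(ens_maps)
    write_overlap(ov,
                  csv_path = add_output(file.path(config$out_dir,
                                                  "overlap.csv")),
                  json_path = add_output(file.path(config$out_dir,
                                                   "overlap.json")))
    manifest$overlap <- list(
      schoener_d = as.list(as.data.frame(ov$schoener_d)))
    log_stage("overlap", list(pairs = choose(length(ens_maps), 2)), t0)
  } else if (config$overlap) {
    message("[overlap] skipped: only one species configured")
    manifest$stages[["overlap"]] <- list(skipped = "single species")
  }

  manifest$total_seconds <- round(proc.time()[["elapsed"]] - t_all, 2)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

model_one_species <- function(sp, config, stack, manifest_log, add_output) {
  out_dir <- config$out_dir
  # ingest / deduplicate / thin
  t0 <- proc.time()[["elapsed"]]
  occ <- read_occurrences(config$occurrences[[sp]],
                          x_col = config$coord_cols[1],
                          y_col = config$coord_cols[2],
                          species = sp, crs = config$crs)
  n_raw <- nrow(occ)
  occ <- deduplicate(occ, grid = stack)
  n_dedup <- nrow(occ)
  occ <- spatial_thin(occ, min_dist = config$thin_dist,
                      seed = derive_seed(config$seed, paste0("thin:", sp)),
                      n_repeats = config$thin_repeats)
  n_thin <- nrow(occ)
  add_output(write_occurrences(
    occ, file.path(out_dir, paste0("occ_", sp, "_thinned.csv"))))
  manifest_log(paste0("records:", sp),
               list(raw = n_raw, deduplicated = n_dedup,
                    thinned = n_thin), t0)

  # background, split, predictor tables
  t0 <- proc.time()[["elapsed"]]
  bg <- sample_background(stack,
                          min(config$background_n,
                              length(valid_cells(stack)) - n_thin),
                          seed = derive_seed(config$seed,
                                             paste0("background:", sp)),
                          exclude = occ)
  parts <- split_train_test(occ, config$train_fraction,
                            seed = derive_seed(config$seed,
                                               paste0("split:", sp)))
  bg_parts <- split_train_test(bg, config$train_fraction,
                               seed = derive_seed(config$seed,
                                                  paste0("splitbg:", sp)))
  tab <- list(
    pres_train = extract_env_values(parts$train, stack),
    pres_test = extract_env_values(parts$test, stack),
    bg_train = extract_env_values(bg_parts$train, stack),
    bg_test = extract_env_values(bg_parts$test, stack))
  manifest_log(paste0("split:", sp),
               list(train = nrow(tab$pres_train),
                    test = nrow(tab$pres_test),
                    background = nrow(bg)), t0)

  # per-algorithm fits + evaluation
  models <- list(); evals <- list(); maps <- list()
  for (alg in config$algorithms) {
    t0 <- proc.time()[["elapsed"]]
    m <- fit_sdm(alg, tab$pres_train, tab$bg_train,
                 params = config$model_params[[alg]] %||% list(),
                 seed = derive_seed(config$seed,
                                    paste0("fit:", sp, ":", alg)))
    maps[[alg]] <- predict_suitability(m, stack)
    ev <- evaluate_scores(predict_sdm(m, tab$pres_test),
                          predict_sdm(m, tab$bg_test),
                          landscape_scores =
                            maps[[alg]]$values[valid_cells(stack)])
    models[[alg]] <- m; evals[[alg]] <- ev
    add_output(write_ascii_grid(
      maps[[alg]], file.path(out_dir,
                             paste0("suit_", sp, "_", alg, ".asc"))))
    manifest_log(paste0("fit:", sp, ":", alg),
                 list(auc = round(ev$auc, 4), tss = round(ev$tss, 4)), t0)
  }

  # ensemble
  t0 <- proc.time()[["elapsed"]]
  tss_w <- if (config$ensemble_rule == "tss")
    vapply(evals, `[[`, numeric(1), "tss") else NULL
  ens_map <- ensemble_combine(maps, tss = tss_w)
  ens <- sdm_ensemble(models, tss = tss_w)
  ens_ev <- evaluate_scores(
    predict_sdm(ens, tab$pres_test), predict_sdm(ens, tab$bg_test),
    landscape_scores = ens_map$values[valid_cells(stack)])
  add_output(write_ascii_grid(
    ens_map, file.path(out_dir, paste0("suit_", sp, "_ensemble.asc"))))
  eval_df <- do.call(rbind, lapply(c(evals, list(ensemble = ens_ev)),
                                   function(e) as.data.frame(unclass(e))))
  eval_df <- cbind(model = rownames(eval_df), eval_df)
  add_output(write_eval_json(eval_df,
                             file.path(out_dir,
                                       paste0("eval_", sp, ".json"))))
  manifest_log(paste0("ensemble:", sp),
               list(auc = round(ens_ev$auc, 4),
                    boyce = round(ens_ev$boyce, 4)), t0)

  # response curves from the GLM member (falls back to the first member)
  t0 <- proc.time()[["elapsed"]]
  rc_model <- models[["glm"]] %||% models[[1]]
  curves <- lapply(rc_model$predictors, function(p)
    response_curve(rc_model, p))
  rc_df <- do.call(rbind, Map(function(cv, p)
    data.frame(predictor = p, value = cv$value,
               suitability = cv$suitability),
    curves, rc_model$predictors))
  add_output({
    p <- file.path(out_dir, paste0("response_curves_", sp, ".csv"))
    utils::write.csv(rc_df, p, row.names = FALSE); p
  })

  # permutation importance of the ensemble
  imp <- variable_importance(
    ens, rbind(tab$pres_train, tab$bg_train),
    seed = derive_seed(config$seed, paste0("importance:", sp)))
  add_output({
    p <- file.path(out_dir, paste0("importance_", sp, ".json"))
    jsonlite::write_json(as.list(unclass(imp)), p, auto_unbox = TRUE,
                         digits = NA); p
  })

  # binary map + suitable area at the ensemble max-TSS threshold
  ba <- binarize_and_area(ens_map, ens_ev$threshold)
  add_output(write_ascii_grid(
    ba$binary, file.path(out_dir, paste0("binary_", sp, ".asc"))))
  manifest_log(paste0("area:", sp),
               list(threshold = round(ba$threshold, 4),
                    area_km2 = ba$area_km2), t0)

  list(summary = list(records = c(raw = n_raw, deduplicated = n_dedup,
                                  thinned = n_thin),
                      evaluation = eval_df,
                      importance = as.list(unclass(imp)),
                      area_km2 = ba$area_km2,
                      threshold = ba$threshold),
       ensemble_map = ens_map)
}

write_eval_json <- function(eval_df, path) {
  jsonlite::write_json(eval_df, path, dataframe = "rows", digits = NA)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a packaged synthetic demonstration scenario
#'
#' `"two-prey-demo"` emulates a predator-like species plus two prey species
#' of differing niche similarity on a 200 x 200 km synthetic landscape:
#' four correlated predictor rasters (Bio5, Bio6, Bio12, TH), three
#' occurrence CSVs (45, 200 and 110 records — sample sizes typical of
#' regional presence-only studies), and a ready-to-run YAML config.
#'
#' @param scenario_name Name of a known scenario (`"two-prey-demo"`).
#' @param out_dir Directory to write the fixture set into.
#' @param seed Integer seed (default 1).
#' @return Path to the written config file, invisibly; the fixture file
#'   paths are attached as attribute `files`.
#' @export
make_demo <- function(scenario_name, out_dir, seed = 1L) {
  known <- "two-prey-demo"
  if (!scenario_name %in% known)
    stop("unknown scenario '", scenario_name, "'; known: ",
         paste(known, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  sc <- demo_scenario(seed)
  stack <- generate_env_stack(sc)
  files <- character(0)
  for (nm in names(stack)) {
    p <- file.path(out_dir, paste0(nm, ".asc"))
    write_ascii_grid(stack[[nm]], p)
    files <- c(files, p)
  }
  spp <- demo_species()
  counts <- c(predator = 45, goatlike_prey = 200, gazellelike_prey = 110)
  for (sp in names(spp)) {
    suit <- suitability_surface(spp[[sp]], stack)
    occ <- sample_presences(suit, counts[[sp]],
                            seed = derive_seed(seed, paste0("demo:", sp)),
                            species = sp)
    p <- file.path(out_dir, paste0("occ_", sp, ".csv"))
    write_occurrences(occ, p)
    files <- c(files, p)
  }
  cfg <- list(
    occurrences = as.list(stats::setNames(
      file.path(out_dir, paste0("occ_", names(spp), ".csv")), names(spp))),
    rasters = as.list(stats::setNames(
      file.path(out_dir, paste0(names(stack), ".asc")), names(stack))),
    out_dir = file.path(out_dir, "results"),
    seed = as.integer(seed), crs = "projected",
    thin_dist = 5000, vif_threshold = 10,
    train_fraction = 0.8, background_n = 10000,
    ensemble_rule = "uniform", overlap = TRUE)
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(structure(cfg_path, files = c(files, cfg_path)))
}

#' Packaged synthetic study conditions
#'
#' The canonical synthetic landscape used by the packaged demo and the
#' validation runs: four predictors in realistic units for a semi-arid
#' plateau flanked by wet mountains — Bio5 (max temperature of the warmest
#' month, 10-50 °C), Bio6 (min temperature of the coldest month, -25-10
#' °C), Bio12 (annual precipitation, 50-2000 mm: arid interior to wet
#' coastal mountains, so a 600 mm optimum sits in the wetter tail of the
#' landscape), TH (topographic heterogeneity, 0-300 m), on a 200 x 200
#' grid of 1 km projected cells. Predictors are uncorrelated by default so
#' permutation importance of an informative predictor is unambiguous;
#' `correlated = TRUE` adds the mild climate correlations typical of real
#' bioclimatic layers.
#'
#' @param seed Integer seed.
#' @param nrow,ncol Grid shape (default 200 x 200).
#' @param correlated Use a mildly correlated predictor set.
#' @return A `synthetic_scenario`.
#' @export
study_scenario <- function(seed, nrow = 200, ncol = 200,
                           correlated = FALSE) {
  R <- if (correlated) {
    matrix(c(1, 0.5, -0.3, 0,
             0.5, 1, -0.2, 0,
             -0.3, -0.2, 1, 0.2,
             0, 0, 0.2, 1), 4, 4, byrow = TRUE)
  } else NULL
  synthetic_scenario(
    predictors = list(Bio5 = c(10, 50), Bio6 = c(-25, 10),
                      Bio12 = c(50, 2000), TH = c(0, 300)),
    correlation = R, nrow = nrow, ncol = ncol, cellsize = 1000,
    crs = "projected", smooth_sigma = 5, seed = seed)
}

#' Packaged virtual species
#'
#' Named virtual species used across the demo and validation runs:
#' \describe{
#'   \item{montane}{Gaussian niche on annual precipitation only (optimum
#'     600 mm, sigma 75 mm) — the single-informative-predictor species
#'     used for response-curve and importance recovery.}
#'   \item{predator}{Montane-wet two-predictor niche: Bio12 (600, 75) and
#'     Bio5 (30 °C, 8).}
#'   \item{goatlike}{Very similar montane niche: Bio12 (620, 85), Bio5
#'     (28, 8).}
#'   \item{gazellelike}{Arid-hot niche widely separated from the montane
#'     species (>= 3 sigma on the precipitation optimum plus a warm
#'     temperature shift): Bio12 (250, 100), Bio5 (40, 8).}
#' }
#'
#' @param which Species name.
#' @return A `virtual_species`.
#' @export
study_species <- function(which = c("montane", "predator", "goatlike",
                                    "gazellelike")) {
  which <- match.arg(which)
  switch(which,
    montane = virtual_species(list(
      Bio12 = list(kind = "gaussian", optimum = 600, width = 75))),
    predator = virtual_species(list(
      Bio12 = list(kind = "gaussian", optimum = 600, width = 75),
      Bio5 = list(kind = "gaussian", optimum = 30, width = 8))),
    goatlike = virtual_species(list(
      Bio12 = list(kind = "gaussian", optimum = 620, width = 85),
      Bio5 = list(kind = "gaussian", optimum = 28, width = 8))),
    gazellelike = virtual_species(list(
      Bio12 = list(kind = "gaussian", optimum = 250, width = 100),
      Bio5 = list(kind = "gaussian", optimum = 40, width = 8))))
}

demo_scenario <- function(seed) study_scenario(seed, correlated = TRUE)

demo_species <- function() {
  list(predator = study_species("predator"),
       goatlike_prey = study_species("goatlike"),
       gazellelike_prey = study_species("gazellelike"))
}
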