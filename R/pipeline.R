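# End-to-end experiment orchestration: simulate (or ingest) a seascape,
# build per-scale predictor stacks, fit both algorithms per species x scale,
# evaluate against an independent validation survey, and emit suitability
# maps, report tables, a manifest and a log from a single config.

#' Habitat suitability map from a fitted model
#'
#' Predicts every valid cell of a predictor stack and scales the result to
#' 0--100 (0 = absence, 100 = highest probability of presence): the BRT
#' occurrence probability or the MaxEnt logistic output, times 100.
#'
#' @param model a [brt] or [maxent] model.
#' @param stack a `predictor_stack` whose layers match the training schema.
#' @return A [raster_grid] on the 0--100 scale (nodata where any layer is
#'   nodata).
#' @export
suitability_map <- function(model, stack) {
  stopifnot(inherits(stack, "predictor_stack"))
  vals <- sapply(stack$layers, function(g) as.vector(g$values))
  colnames(vals) <- names(stack$layers)
  ok <- stats::complete.cases(vals)
  pred <- rep(NA_real_, nrow(vals))
  pred[ok] <- if (inherits(model, "maxent"))
    predict(model, vals[ok, , drop = FALSE], type = "logistic")
  else predict(model, vals[ok, , drop = FALSE])
  ref <- stack$layers[[1]]
  grid_like(ref, matrix(100 * pred, nrow(ref$values)))
}

#' Configuration of a full seascape modelling experiment
#'
#' Bundles every knob of [run_experiment()]. All stochastic stages derive
#' their seeds from `seed`, so a config fully determines the result bundle.
#'
#' @param seascape a [seascape_params()] (its own seed is overridden by
#'   `seed`).
#' @param species named list of [species_response()] objects.
#' @param radii focal radii in meters (default c(5, 25, 50, 100, 300)).
#' @param truth_radius radius of the stack on which the ground-truth
#'   responses are evaluated (default the smallest radius).
#' @param n_sites training survey size.
#' @param n_validation_sites independent validation survey size (default
#'   360).
#' @param allocation hard/soft stratum allocation of sites.
#' @param shelf_edge_depth depth of the shelf-edge contour (m).
#' @param brt named list of arguments passed to [brt()].
#' @param maxent named list of arguments passed to [maxent()] /
#'   [cv_maxent()].
#' @param n_background background cells for MaxEnt.
#' @param threshold_pct suitability threshold for map accuracy (default 10).
#' @param cv_folds folds for model evaluation.
#' @param compute_interactions fit pairwise interaction matrices (slower).
#' @param output_dir directory for artifacts, or NULL to skip writing.
#' @param seed master seed.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(seascape = seascape_params(),
                              species = list(
                                coney = species_response(
                                  steps = list(dist_to_shelf =
                                                 c(location = 2000, jump = -4)),
                                  linear = c(slope_of_slope = 0.08),
                                  target_prevalence = 0.1)),
                              radii = c(5, 25, 50, 100, 300),
                              truth_radius = min(radii),
                              n_sites = 1000, n_validation_sites = 360,
                              allocation = c(0.5, 0.5),
                              shelf_edge_depth = 45,
                              brt = list(learning_rate = 0.05,
                                         tree_complexity = 3,
                                         max_trees = 500,
                                         cv_eval_stride = 25),
                              maxent = list(),
                              n_background = 5000, threshold_pct = 10,
                              cv_folds = 10, compute_interactions = FALSE,
                              output_dir = NULL, seed = 1) {
  if (!length(radii)) stop("radii must be nonempty")
  if (!truth_radius %in% radii) stop("truth_radius must be one of radii")
  if (is.null(names(species)) || any(names(species) == ""))
    stop("species must be a named list")
  structure(as.list(environment()), class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' The file may set any [experiment_config()] argument; `seascape` is given
#' as a mapping of [seascape_params()] fields and each entry of `species`
#' as a mapping of [species_response()] fields.
#'
#' @param path YAML file.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(y$seascape))
    args$seascape <- do.call(seascape_params, y$seascape)
  if (!is.null(y$species))
    args$species <- lapply(y$species, function(sp) {
      if (!is.null(sp$linear)) sp$linear <- unlist(sp$linear)
      if (!is.null(sp$steps)) sp$steps <- lapply(sp$steps, unlist)
      do.call(species_response, sp)
    })
  do.call(experiment_config, args)
}

#' Run a full multi-scale distribution modelling experiment
#'
#' Simulates the seascape, builds the per-scale predictor stacks, simulates
#' each species over a stratified-random training survey, fits BRT and
#' MaxEnt at every scale, evaluates cross-validated AUC, variable
#' importance, (optionally) pairwise interaction strength and
#' partial-dependence curves for the top four predictors, projects 0--100
#' suitability maps, and scores threshold-based map accuracy against an
#' independently simulated validation survey. When `output_dir` is set, all
#' artifacts (ASCII grids, CSV tables, partial-dependence curves, a
#' deterministic log and an md5 manifest) are written there.
#'
#' @param config an [experiment_config()].
#' @return A result bundle (list): `tables` (AUC, BRT settings, map
#'   accuracy), `models`, `maps`, `importance`, `interactions`, `pd_curves`,
#'   `surveys`, `stacks`, and `manifest` when written. The AUC table flags
#'   the best scale per species and algorithm.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  log <- character()
  say <- function(...) log <<- c(log, sprintf(...))
  seed <- config$seed
  say("master seed: %d", seed)

  params <- config$seascape
  params$seed <- seed
  say("seascape: %d x %d cells @ %g m", params$extent_cells[1],
      params$extent_cells[2], params$cell_size_m)
  bathy <- generate_bathymetry(params)
  masks <- make_masks(bathy, config$shelf_edge_depth)
  morph <- compute_morphometrics(bathy)
  sc <- scale_config(radii_m = sort(config$radii))
  stacks <- build_stacks(morph, masks, sc)
  strata <- seascape_strata(bathy)
  train_sites <- sample_survey_sites(bathy, config$n_sites,
                                     config$allocation, strata,
                                     seed = seed + 1L)
  valid_sites <- sample_survey_sites(bathy, config$n_validation_sites,
                                     config$allocation, strata,
                                     seed = seed + 2L)
  say("surveys: %d training, %d validation sites",
      nrow(train_sites), nrow(valid_sites))
  truth_stack <- stacks[[paste0("r", config$truth_radius)]]

  auc_rows <- list(); set_rows <- list(); acc_rows <- list()
  models <- list(); maps <- list(); importance <- list()
  interactions <- list(); pd_curves <- list(); surveys <- list()

  for (sp in names(config$species)) {
    resp <- config$species[[sp]]
    train <- simulate_species(truth_stack, train_sites, resp,
                              seed = seed + 10L)
    valid <- simulate_species(truth_stack, valid_sites, resp,
                              seed = seed + 11L)
    surveys[[sp]] <- list(train = train, validation = valid)
    say("species %s: prevalence %.3f (train), %.3f (validation)",
        sp, mean(train$present), mean(valid$present))
    for (r in sort(config$radii)) {
      key <- paste(sp, r, sep = "_r")
      stack <- stacks[[paste0("r", r)]]
      X <- extract_features(stack, train)
      yv <- train$present[attr(X, "kept")]

      bargs <- c(list(x = X, y = yv, cv_folds = config$cv_folds,
                      seed = seed + 20L), config$brt)
      bfit <- do.call(brt, bargs)
      bmap <- suitability_map(bfit, stack)
      bacc <- map_accuracy(bmap, valid, config$threshold_pct)

      bg <- sample_background(stack, config$n_background, seed = seed + 30L)
      pres <- X[yv == 1, , drop = FALSE]
      margs <- c(list(presence = pres, background = bg), config$maxent)
      mfit <- do.call(maxent, margs)
      mcv <- do.call(cv_maxent,
                     c(list(presence = pres, background = bg,
                            k = config$cv_folds, seed = seed + 40L),
                       config$maxent))
      mmap <- suitability_map(mfit, stack)
      macc <- map_accuracy(mmap, valid, config$threshold_pct)

      models[[key]] <- list(brt = bfit, maxent = mfit)
      maps[[key]] <- list(brt = bmap, maxent = mmap)
      imp <- variable_importance(bfit)
      importance[[key]] <- imp
      if (config$compute_interactions)
        interactions[[key]] <- interaction_strength(bfit)
      top4 <- names(imp)[seq_len(min(4, length(imp)))]
      pd_curves[[key]] <- do.call(rbind, lapply(top4, function(v) {
        pd <- partial_dependence(bfit, v)
        data.frame(species = sp, scale = r, predictor = v,
                   value = pd[[1]], fit = pd$fit)
      }))

      auc_rows[[key]] <- data.frame(
        species = sp, scale = r,
        brt_auc = bfit$cv$auc_mean, brt_auc_se = bfit$cv$auc_se,
        maxent_auc = mcv$auc_mean, maxent_auc_se = mcv$auc_se)
      set_rows[[key]] <- data.frame(
        species = sp, scale = r, n_trees = bfit$n_trees,
        learn_rate = bfit$learning_rate, tc = bfit$tree_complexity,
        cv_deviance = bfit$cv$deviance, se = bfit$cv$deviance_se)
      acc_rows[[key]] <- data.frame(
        species = sp, scale = r, presence_sites = bacc$n_presence_sites,
        brt_pct_correct = bacc$map_accuracy_pct,
        brt_pct_misclassified = bacc$misclassified_pct,
        maxent_pct_correct = macc$map_accuracy_pct,
        maxent_pct_misclassified = macc$misclassified_pct)
      say("%s r=%gm: BRT nt %d, CV AUC %.3f | MaxEnt CV AUC %.3f | map %% %.1f/%.1f",
          sp, r, bfit$n_trees, bfit$cv$auc_mean, mcv$auc_mean,
          bacc$map_accuracy_pct, macc$map_accuracy_pct)
    }
  }

  auc <- do.call(rbind, auc_rows); rownames(auc) <- NULL
  # flag the best-performing scale per species for each algorithm
  auc$brt_best <- stats::ave(auc$brt_auc, auc$species,
                             FUN = function(v) v == max(v)) == 1
  auc$maxent_best <- stats::ave(auc$maxent_auc, auc$species,
                                FUN = function(v) v == max(v)) == 1
  settings <- do.call(rbind, set_rows); rownames(settings) <- NULL
  accuracy <- do.call(rbind, acc_rows); rownames(accuracy) <- NULL

  bundle <- list(tables = list(auc = auc, settings = settings,
                               accuracy = accuracy),
                 models = models, maps = maps, importance = importance,
                 interactions = interactions, pd_curves = pd_curves,
                 surveys = surveys, stacks = stacks, bathymetry = bathy,
                 masks = masks, config = config, log = log)
  if (!is.null(config$output_dir))
    bundle$manifest <- write_bundle(bundle, config$output_dir)
  invisible(bundle)
}

# write all artifacts; returns the manifest data frame
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wr <- function(p) { paths <<- c(paths, p); p }
  write_ascii_grid(bundle$bathymetry, wr(file.path(dir, "bathymetry.asc")))
  write_ascii_grid(bundle$masks$shoreline, wr(file.path(dir, "mask_shoreline.asc")))
  write_ascii_grid(bundle$masks$shelf, wr(file.path(dir, "mask_shelf.asc")))
  for (sp in names(bundle$surveys)) {
    write_survey_csv(bundle$surveys[[sp]]$train,
                     wr(file.path(dir, sprintf("survey_%s_train.csv", sp))))
    write_survey_csv(bundle$surveys[[sp]]$validation,
                     wr(file.path(dir, sprintf("survey_%s_validation.csv", sp))))
  }
  for (key in names(bundle$maps)) {
    write_ascii_grid(bundle$maps[[key]]$brt,
                     wr(file.path(dir, sprintf("suitability_brt_%s.asc", key))),
                     digits = 6)
    write_ascii_grid(bundle$maps[[key]]$maxent,
                     wr(file.path(dir, sprintf("suitability_maxent_%s.asc", key))),
                     digits = 6)
  }
  report_tables(bundle, dir)
  paths <- c(paths, file.path(dir, c("table_auc.csv", "table_brt_settings.csv",
                                     "table_map_accuracy.csv")))
  pd <- do.call(rbind, bundle$pd_curves)
  utils::write.csv(pd, wr(file.path(dir, "partial_dependence.csv")),
                   row.names = FALSE)
  writeLines(bundle$log, wr(file.path(dir, "run.log")))
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)))
  manifest <- manifest[order(manifest$file), ]
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Report tables of an experiment bundle
#'
#' Three CSV-ready tables: cross-validated AUC by species and scale (with
#' best-scale flags per algorithm), the selected BRT settings
#' (`species, scale, n_trees, learn_rate, tc, cv_deviance, se`), and
#' threshold-based map accuracy (percent correct / misclassified per
#' algorithm, with an arithmetic mean row).
#'
#' @param bundle a result bundle from [run_experiment()].
#' @param dir optional directory to write `table_auc.csv`,
#'   `table_brt_settings.csv` and `table_map_accuracy.csv` into.
#' @return Named list of the three data frames.
#' @export
report_tables <- function(bundle, dir = NULL) {
  if (!length(bundle$tables$auc)) stop("empty result bundle")
  acc <- bundle$tables$accuracy
  num <- c("presence_sites", "brt_pct_correct", "brt_pct_misclassified",
           "maxent_pct_correct", "maxent_pct_misclassified")
  mean_row <- data.frame(species = "Mean", scale = NA,
                         as.list(colMeans(acc[, num])))
  accuracy <- rbind(acc, mean_row)
  out <- list(auc = bundle$tables$auc, settings = bundle$tables$settings,
              accuracy = accuracy)
  if (!is.null(dir)) {
    utils::write.csv(out$auc, file.path(dir, "table_auc.csv"),
                     row.names = FALSE)
    utils::write.csv(out$settings, file.path(dir, "table_brt_settings.csv"),
                     row.names = FALSE)
    utils::write.csv(out$accuracy, file.path(dir, "table_map_accuracy.csv"),
                     row.names = FALSE)
  }
  out
}
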