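# End-to-end orchestration: simulate -> composite -> segment -> harmonic ->
# stack -> sample -> train -> predict -> assemble -> summarize -> validate,
# with optional stage caching and a run manifest.

#' Pipeline configuration
#'
#' One configuration object drives the whole run; [runPipeline()] and the
#' per-stage command-line subcommands accept the same structure (YAML via
#' [loadPipelineConfig()]).
#'
#' @param n_rows,n_cols scene grid size
#' @param year_start,year_end mapped year span
#' @param obs_per_year,noise_sd scene observation density and noise
#' @param seed master seed; all stage seeds derive from it
#' @param n_plots calibration/validation sample size
#' @param sample_cap per-stratum allocation cap (NA = none)
#' @param k_folds validation folds
#' @param num_trees,min_node,mtry random-forest hyperparameters (NA mtry =
#'   sqrt rule)
#' @param feature_selection "none", "prune" (correlation filter) or "rfecv"
#'   (correlation filter then grouped recursive elimination)
#' @param tune_grid optional hyperparameter grid data.frame (num_trees,
#'   min_node, mtry) evaluated by grouped grid search
#' @param rules assembly rule list (see [assembleMap()]); the default
#'   forbids change classes over the water mask
#' @return a named list of class `PipelineConfig`
#' @export
pipelineConfig <- function(n_rows = 32L, n_cols = 32L, year_start = 1994L,
                           year_end = 2023L, obs_per_year = 15L,
                           noise_sd = 0.01, seed = 1L, n_plots = 250L,
                           sample_cap = NA, k_folds = 10L,
                           num_trees = 300L, min_node = 5L, mtry = NA,
                           feature_selection = "prune", tune_grid = NULL,
                           rules = NULL) {
  if (is.null(rules))
    rules <- lapply(c("Fast Loss", "Slow Loss", "Gain"), function(cl)
      list(class = cl, mask = "water", action = "forbid"))
  structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    year_start = as.integer(year_start), year_end = as.integer(year_end),
    obs_per_year = as.integer(obs_per_year), noise_sd = noise_sd,
    seed = as.integer(seed), n_plots = as.integer(n_plots),
    sample_cap = sample_cap, k_folds = as.integer(k_folds),
    num_trees = as.integer(num_trees), min_node = as.integer(min_node),
    mtry = mtry, feature_selection = feature_selection,
    tune_grid = tune_grid, rules = rules), class = "PipelineConfig")
}

#' Load a pipeline configuration from YAML
#' @param path YAML file with keys matching [pipelineConfig()] arguments
#' @export
loadPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipelineConfig, y[intersect(names(y),
                                      names(formals(pipelineConfig)))])
}

# label table for the three products from truth records
productLabels <- function(truth) {
  data.frame(
    Change = crosswalkChange(truth$change_process, 3L),
    `Land Cover` = crosswalkLandCover(truth$primary_cover,
                                      truth$secondary_covers, level = 4L),
    `Land Use` = truth$land_use,
    check.names = FALSE, stringsAsFactors = FALSE)
}

# training/validation table: one row per sampled plot-year with complete
# features
buildTrainingTable <- function(cube, truth, sample_df, design) {
  years <- mapYears(cube)
  vals <- featureValues(cube)
  nrec <- nrow(sample_df) * length(years)
  pixel <- rep(sample_df$pixel, times = length(years))
  plot_id <- rep(sample_df$plot_id, times = length(years))
  stratum <- rep(sample_df$stratum, times = length(years))
  year <- rep(years, each = nrow(sample_df))
  X <- matrix(NA_real_, nrec, dim(vals)[3],
              dimnames = list(NULL, featureRegistry(cube)$name))
  yi <- match(year, years)
  for (k in seq_len(dim(vals)[3]))
    X[, k] <- vals[cbind(pixel, yi, k)]
  complete <- stats::complete.cases(X) & cube@complete[cbind(pixel, yi)]
  key <- paste(truth$plot_id, truth$year)
  ti <- match(paste(pixel, year), key)
  labels <- productLabels(truth[ti, ])
  d <- designTable(design)
  w <- d$inv_weight[match(stratum, d$name)]
  keep <- complete & !is.na(ti)
  list(X = X[keep, , drop = FALSE], labels = labels[keep, , drop = FALSE],
       plot_id = plot_id[keep], stratum = stratum[keep], weight = w[keep],
       pixel = pixel[keep], year = year[keep])
}

#' Run the full mapping pipeline on a synthetic scene
#'
#' Executes every stage end to end and returns all artifacts. With an
#' `out_dir`, each stage's output is cached as an RDS file and reused on
#' re-runs (delete a stage file to recompute just that stage); a manifest
#' with seeds, parameters and output hashes is written alongside.
#'
#' @param config a [pipelineConfig()] list
#' @param out_dir cache/output directory, or NULL for no persistence
#' @param force recompute even when cached outputs exist
#' @param quiet suppress stage messages
#' @return named list of stage artifacts (scene, composites, lt, ccdc,
#'   cube, sampling, models, confidences, maps, summaries, validation,
#'   manifest)
#' @export
runPipeline <- function(config = pipelineConfig(), out_dir = NULL,
                        force = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list(),
                   config = unclass(config)[setdiff(names(config),
                                                    c("tune_grid", "rules"))])
  note <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, fun) {
    file <- if (!is.null(out_dir)) file.path(out_dir,
                                             paste0(name, ".rds")) else NULL
    if (!is.null(file) && file.exists(file) && !force) {
      note("[%s] cached", name)
      out <- readRDS(file)
      manifest$stages[[name]] <<- list(file = file, cached = TRUE,
                                       md5 = unname(tools::md5sum(file)))
      return(out)
    }
    note("[%s] running", name)
    out <- tryCatch(fun(), error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    if (!is.null(file)) {
      saveRDS(out, file)
      manifest$stages[[name]] <<- list(file = file, cached = FALSE,
                                       md5 = unname(tools::md5sum(file)))
    } else manifest$stages[[name]] <<- list(cached = FALSE)
    out
  }

  scene <- stage("simulate", function()
    generateScene(demoSceneConfig(config$n_rows, config$n_cols,
                                  config$year_start, config$year_end,
                                  seed = config$seed,
                                  obs_per_year = config$obs_per_year,
                                  noise_sd = config$noise_sd)))
  composites <- stage("composite", function()
    interpolateMissing(annualComposites(scene)))
  lt <- stage("landtrendr", function()
    ltFeatureStack(indexStack(composites), ltParams(), keep_fits = "NBR"))
  ccdc <- stage("ccdc", function()
    ccdcFeatureStack(scene, composites, ccdcParams()))
  cube <- stage("stack", function() {
    terr <- terrainFeatures(sceneDEM(scene))
    buildFeatureMatrix(lt$features, ccdc$features, terr,
                       config$year_start:config$year_end)
  })

  sampling <- stage("sample", function() {
    loss <- deriveLossStratum(lt$segmentations$NBR)
    zone <- as.integer(sceneStrata(scene))
    strat <- zone + 7L * as.integer(loss) # zone x loss cross-strata
    tab <- table(strat)
    cap <- pmin(ifelse(is.na(config$sample_cap), Inf, config$sample_cap),
                as.numeric(tab)) # never allocate more than a stratum holds
    strata_df <- data.frame(name = names(tab),
                            proportion = as.numeric(tab) / sum(tab),
                            cap = cap)
    counts <- allocateSample(strata_df, config$n_plots)
    sample_df <- drawSample(matrix(strat, config$n_rows), counts,
                            seed = childSeed(config$seed, 77L))
    sample_df$stratum <- as.character(sample_df$stratum)
    design <- computeWeights(counts, strata_df$proportion)
    list(sample = sample_df, design = design, strata = strat, loss = loss)
  })

  models <- stage("train", function() {
    tt <- buildTrainingTable(cube, sceneTruth(scene), sampling$sample,
                             sampling$design)
    out <- list(table = tt, products = list())
    for (prod in c("Change", "Land Cover", "Land Use")) {
      y <- tt$labels[[prod]]
      feats <- colnames(tt$X)
      if (config$feature_selection %in% c("prune", "rfecv"))
        feats <- pruneCorrelated(tt$X)
      if (config$feature_selection == "rfecv")
        feats <- selectFeaturesRFE(tt$X[, feats, drop = FALSE], y,
                                   tt$plot_id,
                                   seed = childSeed(config$seed, 11L))
      hp <- list(num_trees = config$num_trees, min_node = config$min_node,
                 mtry = if (is.na(config$mtry)) NULL else config$mtry)
      if (!is.null(config$tune_grid)) {
        best <- tuneHyperparams(tt$X[, feats, drop = FALSE], y, tt$plot_id,
                                config$tune_grid, folds = config$k_folds,
                                seed = childSeed(config$seed, 13L))
        hp <- list(num_trees = best$num_trees, min_node = best$min_node,
                   mtry = if (is.na(best$mtry)) NULL else best$mtry)
      }
      rf <- trainConfidenceModel(tt$X[, feats, drop = FALSE], y,
                                 num_trees = hp$num_trees,
                                 min_node = hp$min_node, mtry = hp$mtry,
                                 seed = childSeed(config$seed, 17L))
      thresholds <- NULL
      if (prod == "Change") {
        oob <- oobVoteConfidence(rf, tt$X[, feats, drop = FALSE])
        thresholds <- selectChangeThresholds(
          oob, y, classes = setdiff(colnames(oob), "Stable"))
      }
      out$products[[prod]] <- list(model = rf, features = feats,
                                   hyperparams = hp,
                                   thresholds = thresholds)
    }
    out
  })

  confidences <- stage("predict", function() {
    lapply(stats::setNames(nm = names(models$products)), function(prod)
      predictConfidenceCube(models$products[[prod]]$model, cube,
                            models$products[[prod]]$features, prod))
  })

  maps <- stage("assemble", function() {
    masks <- sceneMasks(scene)
    lapply(stats::setNames(nm = names(confidences)), function(prod) {
      assembleMap(confidences[[prod]],
                  thresholds = models$products[[prod]]$thresholds,
                  rules = if (prod == "Change") config$rules else list(),
                  masks = masks,
                  stable_class = if (prod == "Change") "Stable" else NULL)
    })
  })

  summaries <- stage("summarize", function()
    list(change_years = changeYearSummaries(maps$Change,
                                            confidences$Change),
         qa = qaStack(composites)))

  validation <- stage("validate", function() {
    tt <- models$table
    folds <- groupedStratifiedKfold(
      data.frame(plot_id = tt$plot_id, stratum = tt$stratum),
      k = config$k_folds, seed = childSeed(config$seed, 23L))
    masks <- sceneMasks(scene)
    d <- designTable(sampling$design)
    props <- stats::setNames(d$proportion, d$name)
    reports <- list()
    for (prod in names(models$products)) {
      pm <- models$products[[prod]]
      y <- tt$labels[[prod]]
      pred <- rep(NA_character_, length(y))
      for (f in sort(unique(folds))) {
        test <- folds[as.character(tt$plot_id)] == f
        rf <- trainConfidenceModel(tt$X[!test, pm$features, drop = FALSE],
                                   y[!test],
                                   num_trees = pm$hyperparams$num_trees,
                                   min_node = pm$hyperparams$min_node,
                                   mtry = pm$hyperparams$mtry,
                                   seed = childSeed(config$seed, 100L + f))
        conf <- predictConfidence(rf, tt$X[test, pm$features, drop = FALSE])
        # mirror map assembly (thresholds + rules) in the assessment
        codes <- assembleRecords(
          conf, tt$pixel[test], thresholds = pm$thresholds,
          rules = if (prod == "Change") config$rules else list(),
          masks = masks,
          stable_class = if (prod == "Change") "Stable" else NULL)
        pred[test] <- colnames(conf)[codes]
      }
      ok <- !is.na(pred)
      levels_for <- switch(prod, "Change" = 3:1, "Land Cover" = 4:1,
                           "Land Use" = 3:1)
      rep_prod <- list()
      for (lv in levels_for) {
        tr_lv <- switch(prod,
                        "Change" = crosswalkChange(y[ok], lv),
                        "Land Cover" = crosswalkLandCover(y[ok], level = lv),
                        "Land Use" = crosswalkLandUse(y[ok], lv))
        pr_lv <- switch(prod,
                        "Change" = crosswalkChange(pred[ok], lv),
                        "Land Cover" = crosswalkLandCover(pred[ok],
                                                          level = lv),
                        "Land Use" = crosswalkLandUse(pred[ok], lv))
        rep_prod[[paste0("level", lv)]] <- weightedAccuracyMetrics(
          tr_lv, pr_lv, weights = tt$weight[ok],
          stratum = tt$stratum[ok], proportions = props)
      }
      reports[[prod]] <- rep_prod
    }
    reports
  })

  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  list(scene = scene, composites = composites, lt = lt, ccdc = ccdc,
       cube = cube, sampling = sampling, models = models,
       confidences = confidences, maps = maps, summaries = summaries,
       validation = validation, manifest = manifest)
}
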