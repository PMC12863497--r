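pipeline_stages <- c("simulate", "subregions", "msi", "train", "evaluate")

config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

#' Pipeline configuration
#'
#' One master seed governs all child streams (cohort generation, mixture
#' fitting, rebalancing, selection, classifier fitting), so an unchanged
#' config reproduces identical results.
#'
#' @param seed master seed.
#' @param cohort a [cohort_recipe()]; its seed is re-derived from `seed`.
#' @param window a [window_spec()].
#' @param supervoxel a [supervoxel_spec()].
#' @param k_candidates mixture size candidates.
#' @param connectivity MSI adjacency (6 or 26).
#' @param resample a [resample_spec()].
#' @param selection a [feature_selection_spec()].
#' @param grid a [model_grid_spec()].
#' @param stages named logical vector toggling
#'   simulate/subregions/msi/train/evaluate.
#' @param out_dir directory for cached stage outputs and the manifest.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, cohort = cohort_recipe(),
                            window = window_spec(),
                            supervoxel = supervoxel_spec(),
                            k_candidates = 1:6, connectivity = 6,
                            resample = resample_spec(),
                            selection = feature_selection_spec(),
                            grid = model_grid_spec(),
                            stages = setNames(rep(TRUE, 5), pipeline_stages),
                            out_dir = tempfile("habitat_run_")) {
  if (!all(names(stages) %in% pipeline_stages) || is.null(names(stages)))
    stop_habitat(paste("unknown stage key:",
                       paste(setdiff(names(stages), pipeline_stages), collapse = ", ")),
                 "habitat_schema_error")
  full <- setNames(rep(FALSE, length(pipeline_stages)), pipeline_stages)
  full[names(stages)] <- stages
  cohort$seed <- child_seed(seed, "cohort")
  resample$seed <- child_seed(seed, "resample")
  selection$seed <- child_seed(seed, "selection")
  grid$seed <- child_seed(seed, "grid")
  structure(list(seed = as.integer(seed), cohort = cohort, window = window,
                 supervoxel = supervoxel, k_candidates = k_candidates,
                 connectivity = connectivity, resample = resample,
                 selection = selection, grid = grid, stages = full,
                 out_dir = out_dir),
            class = "pipeline_config")
}

stage_cache <- function(config, stage, depends_hash, producer) {
  dir.create(file.path(config$out_dir, "cache"), showWarnings = FALSE, recursive = TRUE)
  h <- config_hash(list(stage = stage, depends = depends_hash))
  path <- file.path(config$out_dir, "cache", paste0(stage, "-", h, ".rds"))
  if (file.exists(path)) {
    list(value = readRDS(path), hash = h, cached = TRUE, path = path)
  } else {
    value <- producer()
    saveRDS(value, path)
    list(value = value, hash = h, cached = FALSE, path = path)
  }
}

#' Run the full habitat-MSI workflow
#'
#' Executes the enabled stages in dependency order: simulate a synthetic
#' cohort, window-normalize and oversegment each lesion, fit the cohort-level
#' subregion model on training supervoxels and apply it everywhere, extract
#' MSI feature vectors, rebalance/standardize/select features and train the
#' model grid, then evaluate on the validation and test cohorts. Stage
#' outputs are cached content-addressed under `out_dir/cache`; re-running an
#' unchanged config reuses them and reproduces identical checksums.
#'
#' @param config a [pipeline_config()].
#' @return list with `manifest` (config hash, per-stage hashes, timings) and
#'   `results` (per-stage outputs for the enabled stages).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  st <- config$stages
  manifest <- list(config_hash = config_hash(unclass(config)[setdiff(names(config), "out_dir")]),
                   package_version = as.character(utils::packageVersion("habitatMSI")),
                   stages = list())
  results <- list()
  warnings_log <- character()
  t_stage <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- expr
    list(value = v, seconds = proc.time()[["elapsed"]] - t0)
  }
  need <- function(stage, upstream) {
    stop_habitat(sprintf("stage '%s' requires output of disabled stage '%s'",
                         stage, upstream), "habitat_dependency_error")
  }

  cohort <- NULL
  if (st[["simulate"]]) {
    cc <- stage_cache(config, "simulate", list(cohort = unclass(config$cohort)),
                      function() generate_cohort(config$cohort))
    cohort <- cc$value
    manifest$stages$simulate <- list(hash = cc$hash, cached = cc$cached,
                                     n_cases = nrow(cohort$table))
  }

  subreg <- NULL
  if (st[["subregions"]]) {
    if (is.null(cohort)) need("subregions", "simulate")
    dep <- list(cohort_hash = manifest$stages$simulate$hash,
                window = unclass(config$window),
                supervoxel = unclass(config$supervoxel),
                k = config$k_candidates)
    cc <- stage_cache(config, "subregions", dep, function() {
      maps <- vector("list", length(cohort$cases))
      for (i in seq_along(cohort$cases)) {
        case <- cohort$cases[[i]]
        cropped <- crop_voi(case$volume, case$mask, margin_vox = 2L)
        unit <- window_normalize(cropped$volume, config$window)
        maps[[i]] <- list(sv = compute_supervoxels(unit, cropped$mask, config$supervoxel),
                          hu = cropped$volume)
      }
      train_idx <- which(cohort$table$cohort == "training")
      pooled <- do.call(rbind, lapply(maps[train_idx], function(m) m$sv$phenotypes))
      model <- fit_subregion_model(pooled, config$k_candidates,
                                   seed = child_seed(config$seed, "gmm"))
      labelmaps <- lapply(maps, function(m) assign_subregions(m$sv, model))
      names(labelmaps) <- cohort$table$case_id
      stats <- lapply(seq_along(maps), function(i)
        subregion_stats(labelmaps[[i]], maps[[i]]$hu))
      list(model = model, labelmaps = labelmaps, stats = stats)
    })
    subreg <- cc$value
    manifest$stages$subregions <- list(hash = cc$hash, cached = cc$cached,
                                       k = subreg$model$k)
  }

  feats <- NULL
  if (st[["msi"]]) {
    if (is.null(subreg)) need("msi", "subregions")
    dep <- list(up = manifest$stages$subregions$hash, conn = config$connectivity)
    cc <- stage_cache(config, "msi", dep, function()
      msi_feature_table(subreg$labelmaps, connectivity = config$connectivity))
    feats <- cc$value
    manifest$stages$msi <- list(hash = cc$hash, cached = cc$cached,
                                n_features = ncol(feats) - 1L)
  }

  model <- NULL
  if (st[["train"]]) {
    if (is.null(feats)) need("train", "msi")
    dep <- list(up = manifest$stages$msi$hash,
                resample = unclass(config$resample),
                selection = unclass(config$selection),
                grid = unclass(config$grid))
    cc <- stage_cache(config, "train", dep, function()
      train_msi_model(feats, cohort$table, config))
    model <- cc$value
    manifest$stages$train <- list(hash = cc$hash, cached = cc$cached,
                                  classifier = model$model$classifier,
                                  preprocessor = model$model$preprocessor$method,
                                  n_selected = length(model$selected$features))
  }

  if (st[["evaluate"]]) {
    if (is.null(model)) need("evaluate", "train")
    dep <- list(up = manifest$stages$train$hash)
    cc <- stage_cache(config, "evaluate", dep, function() {
      out <- list()
      for (co in c("training", "validation", "test")) {
        i <- which(cohort$table$cohort == co)
        probs <- predict(model$model, model$features_std[i, , drop = FALSE])
        y <- as.integer(cohort$table$grade[i] == "high")
        out[[co]] <- list(report = eval_report(probs, y, model$model$threshold, co),
                          decision_curve = decision_curve(probs, y),
                          subgroup = subgroup_eval(probs, y,
                                                   cohort$table$diameter_mm[i],
                                                   model$model$threshold))
      }
      out
    })
    results$evaluation <- cc$value
    manifest$stages$evaluate <- list(hash = cc$hash, cached = cc$cached)
  }

  results$cohort <- cohort
  results$subregions <- subreg
  results$msi_features <- feats
  results$model <- model
  manifest$warnings <- warnings_log
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  list(manifest = manifest, results = results)
}

# training-side modeling: SMOTE -> z-score -> RFE+LASSO -> grid
train_msi_model <- function(feats, table, config) {
  fcols <- setdiff(names(feats), "case_id")
  x <- as.matrix(feats[fcols])
  y <- as.integer(table$grade == "high")
  tr <- which(table$cohort == "training")
  va <- which(table$cohort == "validation")

  sm <- smote_resample(x[tr, , drop = FALSE], y[tr], config$resample)
  zs <- zscore_fit_apply(sm$features, all = x)
  sel <- select_features(zs$train, sm$labels, config$selection)
  if (length(sel$features) == 0)
    stop_habitat("no feature survived selection", "habitat_degenerate_error")
  train_std <- zs$train[, sel$features, drop = FALSE]
  all_std <- zs$others$all[, sel$features, drop = FALSE]
  gm <- grid_train(train_std, sm$labels,
                   all_std[va, , drop = FALSE], y[va], config$grid)
  features_std <- as.data.frame(all_std)
  list(model = gm, selected = sel, smote = sm$info,
       features_std = features_std, zscore = list(center = zs$center,
                                                  scale = zs$scale))
}
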