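# End-to-end orchestration: configuration, derived stage seeds, and the
# seeded simulate -> maps -> segment -> features -> select -> predict run.

# mix a seed with an iteration counter without integer overflow
sub_seed <- function(seed, it) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(it) * 9973) %% 2147483629) + 1L
}

#' Deterministic per-stage seed derived from a master seed
#'
#' @param master integer master seed.
#' @param stage stage name.
#' @return a positive integer seed below 2^31, stable across sessions.
#' @export
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483629) + 1L
}

#' Pipeline configuration
#'
#' Bundles the layout, growth and truth settings of the synthetic trial with
#' the thresholds and algorithm settings of every downstream stage. All
#' stage seeds are derived deterministically from the master seed.
#'
#' @param seed master seed.
#' @param layout,growth,truth generator settings (see [field_layout()],
#'   [growth_params()], [synthetic_truth()]).
#' @param soil_threshold NDVI below which a pixel is soil (default 0.1).
#' @param veg_threshold NDVI above which a pixel is plant canopy
#'   (default 0.5).
#' @param roi_radius_m plant ROI radius (default 0.20 m).
#' @param n_levels GLCM gray levels (default 32).
#' @param mode candidate mode, `"all"` (756 variables with the default
#'   dates/maps) or `"first_order"` (200).
#' @param methods selection methods to run.
#' @param repeats selection repeats averaged per method (default 10).
#' @param models prediction model kinds.
#' @param traits traits to analyse.
#' @param train_fraction,cv_folds split and tuning controls.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, layout = field_layout(),
                            growth = growth_params(),
                            truth = synthetic_truth(),
                            soil_threshold = 0.1, veg_threshold = 0.5,
                            roi_radius_m = 0.20, n_levels = 32,
                            mode = "all",
                            methods = c("boruta", "permimp", "ga", "lasso", "rfe"),
                            repeats = 10,
                            models = c("rf", "ridge", "svm"),
                            traits = c("SM", "FW", "FN"),
                            train_fraction = 0.8, cv_folds = 10) {
  stopifnot(soil_threshold >= -1, soil_threshold <= 1,
            veg_threshold >= -1, veg_threshold <= 1, roi_radius_m > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full pipeline on a synthetic trial
#'
#' Simulates the field, derives terrain / plant-height / vegetation-index
#' maps, segments plants and recovers their records against the nominal
#' transplant grid, assembles and normalizes the feature table, runs the
#' configured selection methods per trait with averaged importances, and
#' evaluates the configured prediction models on every selected set.
#' Deterministic for a fixed configuration.
#'
#' @param config a [pipeline_config()].
#' @param stages stages to run through: `"features"` stops after the feature
#'   table; `"select"` adds variable selection; `"predict"` (default) runs
#'   everything.
#' @return list: `sim`, `scene` (with derived maps), `records`, `features`,
#'   `features_norm`, `selections` (per trait, per method), `evaluation`
#'   (grid + evals), `config`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("predict", "select", "features")) {
  stages <- match.arg(stages)
  sim <- generate_field(config$layout, config$growth, config$truth,
                        seed = stage_seed(config$seed, "simulate"),
                        n_levels = config$n_levels)
  scene <- derive_scene_maps(sim$scene, soil_threshold = config$soil_threshold)
  seg_date <- scene$dates[1]
  labels <- segment_plants(get_map(scene, seg_date, "ndvi"),
                           veg_threshold = config$veg_threshold)
  expected <- nominal_positions(config$layout)
  records <- plant_records(labels, expected = expected,
                           roi_radius_m = config$roi_radius_m)
  X <- assemble(scene, records, mode = config$mode, n_levels = config$n_levels)
  Z <- normalize_features(X)
  out <- list(sim = sim, scene = scene, records = records, features = X,
              features_norm = Z, config = config)
  if (stages == "features") return(out)
  yields <- sim$yields[match(records$plant_id, sim$yields$plant_id), ]
  selections <- list()
  for (trait in config$traits) {
    y <- yields[[trait]]
    sel_t <- list()
    for (m in config$methods) {
      args <- list(Z, y, method = m, repeats = config$repeats,
                   seed = stage_seed(config$seed, paste0("select-", m, "-", trait)))
      if (m %in% c("lasso", "ga")) args$cv_folds <- min(config$cv_folds, nrow(Z))
      sel_t[[m]] <- do.call(run_selection, args)
    }
    selections[[trait]] <- sel_t
  }
  out$selections <- selections
  if (stages == "select") return(out)
  sel_sets <- lapply(selections, function(sl) lapply(sl, function(r) r$top_k))
  out$evaluation <- run_matrix(X, yields, sel_sets, models = config$models,
                               traits = config$traits,
                               train_fraction = config$train_fraction,
                               cv_folds = config$cv_folds,
                               seed = stage_seed(config$seed, "predict"))
  out$yields <- yields
  out
}
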