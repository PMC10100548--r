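#' Default end-to-end pipeline configuration
#'
#' Describes a full synthetic study: generate ground truth and raw records,
#' preprocess, fit the hurdle model, predict for the held-out substances and
#' evaluate against the null baseline. The default scale (8 sectors, 30
#' subsectors, 300 substances, 6 properties, 30,000 observations) is large
#' enough for stable parameter recovery while fitting in minutes on one CPU.
#'
#' @param seed Global seed; per-stage seeds are derived from it by stage
#'   name, so stages are individually reproducible.
#' @return Nested configuration list.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    synthetic = list(
      n_sectors = 8L,
      subsectors_per_sector = c(4L, 4L, 4L, 4L, 4L, 4L, 3L, 3L),
      n_substances = 300L,
      n_properties = 6L,
      n_obs = 30000L,
      hyper = synthetic_hyper_config(),
      corruption = list(n_blanks = 20L, n_wipes = 10L, n_nonconvertible = 30L,
                        n_unmappable = 25L, n_ambiguous = 5L, n_outliers = 3L)
    ),
    preprocess = list(z_max = 4, min_detects = 10, test_fraction = 0.1),
    design = list(prune_threshold = 0.85, keep_priority = NULL),
    model = list(method = "laplace", n_draws = 2000L),
    prediction = list(level = 0.95, include_residual = TRUE)
  )
}

check_config <- function(config) {
  known <- c("seed", "synthetic", "preprocess", "design", "model",
             "prediction")
  extra <- setdiff(names(config), known)
  if (length(extra)) {
    abort(sprintf("unknown config block(s): %s", paste(extra, collapse = ", ")))
  }
  for (block in c("seed", "synthetic", "preprocess")) {
    if (is.null(config[[block]])) {
      abort(sprintf("config is missing the `%s` block", block))
    }
  }
  config
}

#' Run the full synthetic study end to end
#'
#' Executes simulate, preprocess, design, fit, predict and evaluate with
#' per-stage seeds derived from the global seed, and optionally writes every
#' intermediate table, the drop log, the fitted model, predictions, the
#' evaluation report and a manifest of seeds and row counts. Two runs with
#' the same configuration produce identical artifacts.
#'
#' @param config Configuration list (see [default_run_config()]) or the path
#'   to a YAML file holding one.
#' @param out_dir Output directory; `NULL` skips writing artifacts.
#' @return (Invisibly) a list with every intermediate object: `hierarchy`,
#'   `substances`, `truth`, `clean`, `raw`, `ledger`, `concordance`,
#'   `observations`, `drop_log`, `train`, `test`, `standardization`,
#'   `retained`, `model`, `null`, `predictions`, `evaluation`, `manifest`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- check_config(config)
  seed <- config$seed
  syn <- config$synthetic
  pp <- config$preprocess

  # --- simulate ------------------------------------------------------------
  hierarchy <- generate_hierarchy(syn$n_sectors, syn$subsectors_per_sector)
  substances <- generate_substances(syn$n_substances,
                                    n_properties = syn$n_properties,
                                    seed = derive_seed(seed, "substances"))
  n_predictors <- syn$n_properties + choose(syn$n_properties, 2L)
  hyper <- syn$hyper %||% synthetic_hyper_config()
  truth <- draw_true_parameters(hierarchy, n_predictors, hyper,
                                seed = derive_seed(seed, "truth"))
  std_all <- standardize(substances)
  clean <- generate_observations(truth, std_all$data, hierarchy, syn$n_obs,
                                 seed = derive_seed(seed, "observations"))
  corr_cfg <- do.call(corruption_config, syn$corruption %||% list())
  raw <- generate_raw_samples(clean, substances, corr_cfg,
                              seed = derive_seed(seed, "raw-samples"))

  # --- preprocess ----------------------------------------------------------
  prep <- preprocess_samples(raw$records, raw$concordance,
                             properties = substances,
                             z_max = pp$z_max %||% 4,
                             min_detects = pp$min_detects %||% 10)
  split <- split_by_substance(prep$observations,
                              test_fraction = pp$test_fraction %||% 0.1,
                              seed = derive_seed(seed, "split"))

  # --- design --------------------------------------------------------------
  train_sub <- substances$substance_id %in% split$train$substance_id
  retained <- prune_correlated(substances,
                               threshold = config$design$prune_threshold %||% 0.85,
                               keep_priority = config$design$keep_priority)
  std <- standardize(substances, fit_rows = train_sub, columns = retained)
  X_train <- build_design_matrix(std$data, split$train)

  # --- fit -----------------------------------------------------------------
  mc <- config$model %||% list()
  mc$seed <- derive_seed(seed, "fit")
  model_cfg <- do.call(model_config, mc)
  model <- fit_hurdle(X_train, split$train, hierarchy, model_cfg,
                      standardization = std$params, properties = retained)

  # --- predict + evaluate --------------------------------------------------
  null <- null_model(split$train)
  predictions <- NULL
  evaluation <- NULL
  if (nrow(split$test) > 0L) {
    level <- config$prediction$level %||% 0.95
    predictions <- stats::predict(
      model, split$test[c("substance_id", "subsector")], substances,
      level = level,
      include_residual = config$prediction$include_residual %||% TRUE,
      seed = derive_seed(seed, "predict")
    )
    conc_mean <- predict_concentration(model,
                                       split$test[c("substance_id", "subsector")],
                                       substances, include_residual = FALSE)
    conc_median <- apply(conc_mean, 2L, stats::median)
    evaluation <- evaluation_report(predictions$p_median, conc_median,
                                    split$test, null)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("airhurdle")),
    seed = seed,
    stage_seeds = list(
      substances = derive_seed(seed, "substances"),
      truth = derive_seed(seed, "truth"),
      observations = derive_seed(seed, "observations"),
      raw_samples = derive_seed(seed, "raw-samples"),
      split = derive_seed(seed, "split"),
      fit = derive_seed(seed, "fit"),
      predict = derive_seed(seed, "predict")
    ),
    rows = list(
      raw_samples = nrow(raw$records),
      clean_observations = nrow(prep$observations),
      train = nrow(split$train),
      test = nrow(split$test)
    ),
    drop_log = prep$drop_log,
    corruption_ledger = raw$ledger
  )

  result <- list(hierarchy = hierarchy, substances = substances,
                 truth = truth, clean = clean, raw = raw$records,
                 ledger = raw$ledger, concordance = raw$concordance,
                 observations = prep$observations, drop_log = prep$drop_log,
                 train = split$train, test = split$test,
                 test_substances = split$test_substances,
                 standardization = std$params, retained = retained,
                 model = model, null = null, predictions = predictions,
                 evaluation = evaluation, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(prep$observations,
                     file.path(out_dir, "observations.csv"), row.names = FALSE)
    utils::write.csv(split$train, file.path(out_dir, "train.csv"),
                     row.names = FALSE)
    utils::write.csv(split$test, file.path(out_dir, "test.csv"),
                     row.names = FALSE)
    utils::write.csv(prep$drop_log, file.path(out_dir, "drop_log.csv"),
                     row.names = FALSE)
    utils::write.csv(raw$ledger, file.path(out_dir, "corruption_ledger.csv"),
                     row.names = FALSE)
    write_hurdle_model(model, file.path(out_dir, "model"))
    if (!is.null(predictions)) {
      utils::write.csv(predictions, file.path(out_dir, "predictions.csv"),
                       row.names = FALSE)
      utils::write.csv(evaluation, file.path(out_dir, "evaluation.csv"),
                       row.names = FALSE)
    }
    manifest_out <- manifest
    manifest_out$drop_log <- NULL
    manifest_out$corruption_ledger <- NULL
    yaml::write_yaml(manifest_out, file.path(out_dir, "manifest.yaml"))
  }
  invisible(result)
}
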