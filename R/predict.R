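# build per-query design rows and subsector indices from a fitted model
query_design <- function(model, queries, properties) {
  if (!all(c("substance_id", "subsector") %in% names(queries))) {
    abort("`queries` must have columns substance_id and subsector")
  }
  novel <- queries$novel %||% rep(FALSE, nrow(queries))
  std <- if (!is.null(model$standardization)) {
    standardize(properties, params = model$standardization,
                columns = model$properties)$data
  } else {
    properties
  }
  keep <- c(intersect(c("substance_id", "molecular_weight"), names(std)),
            model$properties)
  rows <- design_rows(std[keep])
  idx <- match(queries$substance_id, rownames(rows))
  if (anyNA(idx)) {
    abort(sprintf("no property row for substance(s): %s",
                  paste(unique(queries$substance_id[is.na(idx)]), collapse = ", ")))
  }
  if (!identical(colnames(rows), model$detect$coef_names)) {
    abort("property columns do not match the fitted design")
  }
  j <- match(queries$subsector, model$hierarchy$subsector_ids)
  if (any(is.na(j) & !novel)) {
    abort(sprintf(
      "unknown subsector(s) without novel flag: %s",
      paste(unique(queries$subsector[is.na(j) & !novel]), collapse = ", ")))
  }
  list(X = rows[idx, , drop = FALSE], j = j, novel = novel)
}

# linear-predictor draws (n_draws x n_queries) for one stage; novel queries
# get a zeroed subsector intercept (fixed effects only)
stage_eta_draws <- function(pd, qd) {
  beta <- pd$draws[, pd$index$coefficients, drop = FALSE]
  eta <- beta %*% t(qd$X)
  b <- pd$draws[, pd$index$subsectors, drop = FALSE]
  use <- !qd$novel & !is.na(qd$j)
  if (any(use)) {
    eta[, use] <- eta[, use, drop = FALSE] + b[, qd$j[use], drop = FALSE]
  }
  eta
}

#' Posterior draws of detection probability for substance-by-workplace pairs
#'
#' For each query, evaluates `plogis(beta1_j + sum_m beta2_m x_m)` at every
#' posterior draw. Queries flagged `novel = TRUE` use a zeroed subsector
#' intercept (fixed effects only), implementing the option of predicting for
#' workplace types outside the fitted hierarchy; unknown subsectors without
#' that flag are an error.
#'
#' @param model A fitted `hurdle_model`.
#' @param queries Data.frame with `substance_id`, `subsector` and optional
#'   logical `novel`.
#' @param properties Substance-property table on the original (raw) scale;
#'   the model's stored standardization is applied.
#' @return Matrix of detection-probability draws, `n_draws` x `n_queries`.
#' @export
predict_detection <- function(model, queries, properties) {
  qd <- query_design(model, queries, properties)
  stats::plogis(stage_eta_draws(model$detect, qd))
}

#' Posterior draws of conditional log10 air concentration
#'
#' Evaluates the concentration-stage linear predictor at every posterior
#' draw. With `include_residual = TRUE` a Normal(0, sigma_eps) residual is
#' added per draw, giving posterior-predictive draws of a new observation;
#' without it the draws represent the posterior of the conditional mean.
#'
#' @inheritParams predict_detection
#' @param include_residual Add residual noise (posterior predictive)?
#' @param seed Integer seed for the residual noise.
#' @return Matrix of conditional log10 mg/m3 draws, `n_draws` x `n_queries`.
#' @export
predict_concentration <- function(model, queries, properties,
                                  include_residual = FALSE, seed = 1L) {
  qd <- query_design(model, queries, properties)
  eta <- stage_eta_draws(model$concentration, qd)
  if (include_residual) {
    pd <- model$concentration
    sig <- pd$draws[, pd$index$scales[length(pd$index$scales)]]
    noise <- with_seed(seed, {
      matrix(stats::rnorm(length(eta), 0, rep(sig, ncol(eta))),
             nrow(eta), ncol(eta))
    })
    eta <- eta + noise
  }
  eta
}

#' Equal-tailed interval summary of prediction draws
#'
#' @param draws Numeric vector, or matrix with one column per query.
#' @param level Interval level in `[0, 1]`; the summary reports the
#'   `(1-level)/2`, `0.5` and `(1+level)/2` quantiles.
#' @return Data.frame with `median`, `lower`, `upper` and `span`
#'   (`upper - lower`, i.e. orders of magnitude for log10 draws).
#' @export
summarize_prediction <- function(draws, level = 0.95) {
  if (is.null(draws) || length(draws) == 0L) abort("no draws to summarize")
  if (!is.matrix(draws)) draws <- matrix(draws, ncol = 1L)
  probs <- c((1 - level) / 2, 0.5, (1 + level) / 2)
  q <- apply(draws, 2L, stats::quantile, probs = probs, names = FALSE)
  data.frame(median = q[2L, ], lower = q[1L, ], upper = q[3L, ],
             span = q[3L, ] - q[1L, ])
}

#' Group-level prediction summaries
#'
#' Generates per-observation prediction draws, pools them across all
#' observations of each group (sector, subsector or substance) and
#' summarizes detection probability and conditional concentration with
#' medians and equal-tailed intervals — the table behind sector/subsector
#' detection-frequency and concentration figures.
#'
#' @param model A fitted `hurdle_model`.
#' @param observations Observation table carrying the group labels.
#' @param properties Substance-property table (raw scale).
#' @param group_by `"sector"`, `"subsector"` or `"substance"`.
#' @param level Interval level.
#' @param include_residual Posterior-predictive concentration draws?
#' @param seed Seed for residual noise.
#' @return Data.frame with one row per group: pooled summaries of detection
#'   probability (`p_*`) and conditional log10 concentration (`conc_*`),
#'   plus `conc_median_mgm3`, the back-transformed median.
#' @export
summarize_by_group <- function(model, observations, properties,
                               group_by = c("sector", "subsector", "substance"),
                               level = 0.95, include_residual = TRUE,
                               seed = 1L) {
  group_by <- match.arg(group_by)
  key <- switch(group_by,
                sector = observations$sector,
                subsector = observations$subsector,
                substance = observations$substance_id)
  if (is.null(key)) abort(sprintf("observations lack a %s column", group_by))
  queries <- observations[c("substance_id", "subsector")]
  p <- predict_detection(model, queries, properties)
  conc <- predict_concentration(model, queries, properties,
                                include_residual = include_residual,
                                seed = seed)
  groups <- sort(unique(key))
  out <- lapply(groups, function(g) {
    cols <- which(key == g)
    ps <- summarize_prediction(as.vector(p[, cols]), level)
    cs <- summarize_prediction(as.vector(conc[, cols]), level)
    data.frame(group = g, n = length(cols),
               p_median = ps$median, p_lower = ps$lower, p_upper = ps$upper,
               conc_median = cs$median, conc_lower = cs$lower,
               conc_upper = cs$upper, conc_span = cs$span,
               conc_median_mgm3 = 10^cs$median,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  names(res)[1L] <- group_by
  res
}

#' Rank substances for screening
#'
#' Adds descending rank columns by median detection probability and by
#' median conditional concentration, with ties broken by substance id so the
#' ranking is stable under row permutation.
#'
#' @param predictions Data.frame with `substance_id`, `p_median` and a
#'   concentration median column (`conc_median` or `conc_median_log10`).
#' @return The table sorted by detection rank, with `rank_detection` and
#'   `rank_concentration` columns.
#' @export
rank_substances <- function(predictions) {
  conc_col <- intersect(c("conc_median", "conc_median_log10"),
                        names(predictions))[1L]
  if (is.na(conc_col) || !"p_median" %in% names(predictions)) {
    abort("`predictions` needs substance_id, p_median and a conc median column")
  }
  rk <- function(x) {
    ord <- order(-x, predictions$substance_id)
    r <- integer(length(x)); r[ord] <- seq_along(x); r
  }
  predictions$rank_detection <- rk(predictions$p_median)
  predictions$rank_concentration <- rk(predictions[[conc_col]])
  predictions[order(predictions$rank_detection), , drop = FALSE]
}

#' Screening predictions for substance-by-workplace pairs
#'
#' @param object A fitted `hurdle_model`.
#' @param queries Data.frame with `substance_id`, `subsector`, optional
#'   `novel`.
#' @param properties Substance-property table (raw scale).
#' @param level Interval level for the summaries.
#' @param include_residual Posterior-predictive concentration intervals
#'   (default) or conditional-mean intervals.
#' @param seed Seed for residual noise.
#' @param ... Unused.
#' @return Data.frame with the query keys, detection-probability summary
#'   (`p_median`, `p_lower`, `p_upper`), conditional log10-concentration
#'   summary (`conc_median_log10`, `conc_lower`, `conc_upper`, `span`) and
#'   the back-transformed `conc_median_mgm3`.
#' @export
predict.hurdle_model <- function(object, queries, properties, level = 0.95,
                                 include_residual = TRUE, seed = 1L, ...) {
  p <- predict_detection(object, queries, properties)
  conc <- predict_concentration(object, queries, properties,
                                include_residual = include_residual,
                                seed = seed)
  ps <- summarize_prediction(p, level)
  cs <- summarize_prediction(conc, level)
  data.frame(
    substance_id = queries$substance_id, subsector = queries$subsector,
    p_median = ps$median, p_lower = ps$lower, p_upper = ps$upper,
    conc_median_log10 = cs$median, conc_lower = cs$lower,
    conc_upper = cs$upper, span = cs$span,
    conc_median_mgm3 = 10^cs$median,
    stringsAsFactors = FALSE
  )
}
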