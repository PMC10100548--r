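# Fit the two-stage Bayesian hierarchical hurdle model: a logistic stage
# for detect/nondetect on all training observations and a linear stage for
# log10 concentration on the detected subset, both with subsector
# intercepts partially pooled toward sector means and standardized property
# main effects + two-way interactions.

source("analysis/00_config.R")

substances <- read_table("substances.csv")
train <- read_table("train.csv")

retained <- prune_correlated(substances,
                             threshold = CFG$design$prune_threshold)
std <- standardize(substances,
                   fit_rows = substances$substance_id %in% train$substance_id,
                   columns = retained)
X <- build_design_matrix(std$data, train)

hier_codes <- unique(train[c("sector", "subsector")])
hierarchy <- hierarchy_index(
  setNames(hier_codes$sector, hier_codes$subsector)
)

cfg <- model_config(method = CFG$model$method, n_draws = CFG$model$n_draws,
                    seed = derive_seed(SEED, "fit"))
model <- fit_hurdle(X, train, hierarchy, cfg,
                    standardization = std$params, properties = retained)
write_hurdle_model(model, file.path(RESULTS, "model"))

cat(sprintf("Retained %d of %d properties -> %d predictors.\n",
            length(retained), length(setdiff(names(substances),
                                             c("substance_id", "molecular_weight"))),
            ncol(X)))
cat(sprintf("Fitted both stages on %d observations (%d detects), %d draws.\n",
            nrow(train), sum(train$detected), cfg$n_draws))
for (stage in c("detect", "concentration")) {
  pd <- model[[stage]]
  est <- colMeans(pd$draws[, pd$index$coefficients, drop = FALSE])
  top <- head(sort(abs(est), decreasing = TRUE), 3)
  cat(sprintf("  %s stage, largest coefficients: %s\n", stage,
              paste(sprintf("%s=%.2f", names(top), est[names(top)]),
                    collapse = ", ")))
}
cat(sprintf("Posterior mean residual sd (log10 mg/m3): %.3f\n",
            mean(model$concentration$draws[, "sigma_eps"])))
cat(sprintf("Model written to %s.\n", file.path(RESULTS, "model")))
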