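# Evaluate the fitted hurdle model on the held-out substances against the
# null baseline, and check parameter recovery against the known ground
# truth of the simulation.

source("analysis/00_config.R")

model <- read_hurdle_model(file.path(RESULTS, "model"))
substances <- read_table("substances.csv")
train <- read_table("train.csv")
test <- read_table("test.csv")
truth <- read_table("truth_parameters.csv")
predictions <- read_table("predictions.csv")

cond_mean <- predict_concentration(model, test[c("substance_id", "subsector")],
                                   substances, include_residual = FALSE)
conc_median <- apply(cond_mean, 2, median)
report <- evaluation_report(predictions$p_median, conc_median, test,
                            null_model(train))
write_table(report, "evaluation.csv")

recovery <- do.call(rbind, lapply(c("detect", "concentration"), function(st) {
  pd <- model[[st]]
  est <- colMeans(pd$draws[, pd$index$coefficients, drop = FALSE])
  tv <- truth$value[truth$stage == st & truth$component == "coefficient"]
  data.frame(stage = st, r = cor(est, tv),
             rmse = sqrt(mean((est - tv)^2)))
}))
write_table(recovery, "coefficient_recovery.csv")

fmt <- function(metric, scale = 1, digits = 3) {
  sprintf(paste0("%.", digits, "f vs %.", digits, "f (null)"),
          scale * report$model[report$metric == metric],
          scale * report$null[report$metric == metric])
}
cat("Held-out test set, model vs null:\n")
cat("  accuracy (%):        ", fmt("accuracy", 100, 1), "\n")
cat("  AUC:                 ", fmt("auc"), "\n")
cat("  TPR / TNR (%):       ",
    sprintf("%.1f / %.1f", 100 * report$model[report$metric == "tpr"],
            100 * report$model[report$metric == "tnr"]), "\n")
cat("  RMSE on TPs (log10): ", fmt("rmse_tp"), "\n")
cat("  within 1 order (%):  ", fmt("frac_within_k", 100, 1), "\n")
cat("  combined accuracy (%):", fmt("combined_accuracy", 100, 1), "\n")
cat("Coefficient recovery against ground truth:\n")
for (i in seq_len(nrow(recovery))) {
  cat(sprintf("  %-13s r = %.3f, RMSE = %.3f\n", recovery$stage[i],
              recovery$r[i], recovery$rmse[i]))
}
sig <- mean(model$concentration$draws[, "sigma_eps"])
tv <- truth$value[truth$component == "sigma_eps"]
cat(sprintf("Residual sd: posterior mean %.3f vs truth %.2f.\n", sig, tv))
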