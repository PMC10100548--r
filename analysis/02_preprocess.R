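# Clean the raw sample records: keep personal/area samples, convert units
# to log10 mg/m3, map industry codes, aggregate to per-inspection worst
# cases, remove extreme within-substance outliers and sparse subsectors,
# then hold out 10% of substances as the test set.

source("analysis/00_config.R")

raw <- read_table("raw_samples.csv")
concordance <- read_table("concordance.csv")
substances <- read_table("substances.csv")

prep <- preprocess_samples(raw, concordance, properties = substances,
                           z_max = CFG$preprocess$z_max,
                           min_detects = CFG$preprocess$min_detects)
split <- split_by_substance(prep$observations,
                            test_fraction = CFG$preprocess$test_fraction,
                            seed = derive_seed(SEED, "split"))

write_table(prep$observations, "observations.csv")
write_table(prep$drop_log, "drop_log.csv")
write_table(split$train, "train.csv")
write_table(split$test, "test.csv")

cat(sprintf("Raw samples in: %d\n", nrow(raw)))
n <- nrow(raw)
for (i in seq_len(nrow(prep$drop_log))) {
  row <- prep$drop_log[i, ]
  n <- n - row$rows_dropped
  cat(sprintf("  after %-24s (%-32s): %6d rows (-%d)\n",
              row$stage, row$reason, n, row$rows_dropped))
}
cat(sprintf(
  "Split by substance: %d train / %d test observations (%d test substances).\n",
  nrow(split$train), nrow(split$test), length(split$test_substances)))
cat(sprintf("Training detection rate: %.1f%%.\n",
            100 * mean(split$train$detected)))
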