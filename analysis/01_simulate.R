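# Generate the synthetic study: a known ground truth (hierarchical
# intercepts + property coefficients for both hurdle stages), clean
# inspection-level observations, and the corrupted raw sample records the
# preprocessing pipeline will have to clean up.

source("analysis/00_config.R")

syn <- CFG$synthetic
hierarchy <- generate_hierarchy(syn$n_sectors, syn$subsectors_per_sector)
substances <- generate_substances(syn$n_substances,
                                  seed = derive_seed(SEED, "substances"))
truth <- draw_true_parameters(hierarchy, 21, syn$hyper,
                              seed = derive_seed(SEED, "truth"))
std <- standardize(substances)
clean <- generate_observations(truth, std$data, hierarchy, syn$n_obs,
                               seed = derive_seed(SEED, "observations"))
raw <- generate_raw_samples(clean, substances,
                            do.call(corruption_config, syn$corruption),
                            seed = derive_seed(SEED, "raw-samples"))

write_table(substances, "substances.csv")
write_table(raw$records, "raw_samples.csv")
write_table(raw$concordance, "concordance.csv")
write_table(raw$ledger, "corruption_ledger.csv")
write_table(clean, "clean_observations.csv")

truth_rows <- do.call(rbind, lapply(c("detect", "concentration"), function(st) {
  tp <- truth[[st]]
  rbind(
    data.frame(stage = st, component = "coefficient",
               name = paste0("beta", seq_along(tp$coefficients)),
               value = tp$coefficients),
    data.frame(stage = st, component = "subsector_intercept",
               name = names(tp$subsector_intercepts),
               value = unname(tp$subsector_intercepts)),
    data.frame(stage = st, component = "sector_mean",
               name = names(tp$sector_means),
               value = unname(tp$sector_means))
  )
}))
truth_rows <- rbind(truth_rows,
                    data.frame(stage = "concentration", component = "sigma_eps",
                               name = "sigma_eps",
                               value = truth$concentration$sigma_eps))
write_table(truth_rows, "truth_parameters.csv")

cat(sprintf(
  "Simulated %d sectors / %d subsectors, %d substances.\n",
  hierarchy$n_sectors, hierarchy$n_subsectors, nrow(substances)))
cat(sprintf(
  "%d clean observations (%.1f%% nondetects) expanded to %d raw samples;\n",
  nrow(clean), 100 * mean(!clean$detected), nrow(raw$records)))
cat(sprintf("injected junk rows: %s.\n",
            paste(sprintf("%s=%d", raw$ledger$category, raw$ledger$count),
                  collapse = ", ")))
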