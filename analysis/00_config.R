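# Shared configuration for the analysis scripts. Run each script from the
# repository root, in order:
#   Rscript analysis/01_simulate.R
#   Rscript analysis/02_preprocess.R
#   Rscript analysis/03_fit.R
#   Rscript analysis/04_predict.R
#   Rscript analysis/05_evaluate.R

library(airhurdle)

SEED <- 1L
CFG <- default_run_config(seed = SEED)
RESULTS <- "results"
DATA_DIR <- file.path(RESULTS, "data")
FIG_DIR <- file.path(RESULTS, "figures")
for (d in c(RESULTS, DATA_DIR, FIG_DIR)) {
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
}

# industry codes must survive CSV round trips as character
CODE_COLS <- c(sector = "character", subsector = "character",
               industry_code = "character", old_code = "character",
               inspection_id = "character", substance_id = "character")

read_table <- function(name) {
  path <- file.path(DATA_DIR, name)
  cls <- CODE_COLS[intersect(names(CODE_COLS),
                             names(utils::read.csv(path, nrows = 1)))]
  utils::read.csv(path, colClasses = cls)
}

write_table <- function(df, name) {
  utils::write.csv(df, file.path(DATA_DIR, name), row.names = FALSE)
}
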