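# Shared paths and the study seed for the numbered analysis scripts.
# Run the scripts in order from the repository root:
#   Rscript analysis/01_simulate.R && Rscript analysis/02_preprocess.R && ...
# Bulky intermediates (raw curves, full AUC table, sampler trace) live under
# scratch/analysis/; the tables a reader wants live under results/.

suppressPackageStartupMessages(library(hcstopics))

STUDY_SEED <- 1L
DATA_DIR <- "scratch/analysis/data"
MODEL_DIR <- "scratch/analysis/model"
RESULTS_DIR <- "results"
for (d in c(DATA_DIR, MODEL_DIR, RESULTS_DIR))
  dir.create(d, showWarnings = FALSE, recursive = TRUE)

tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("  wrote ", path)
}
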