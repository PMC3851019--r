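#!/usr/bin/env Rscript
# Stage 1 — simulate the screening campaign.
#
# Generates the default synthetic study: 122 drugs x 10 endpoints x
# 4 time points (1/6/24/48 h), 10-point 2-fold dilution series up to
# 200 uM with matched DMSO control curves, and disjoint planted classes
# (early necrosis -> severe-damage endpoint group; late necrosis ->
# DNA Damage/Apoptosis, ramping over time; non-necrosis -> Cell Loss/
# Nuclear Size, mild throughout).

source("analysis/00_common.R")

message("01_simulate: generating synthetic HCS dataset (seed ", STUDY_SEED,
        ")")
ds <- generate_dataset(sim_config(seed = STUDY_SEED))
print(ds)
paths <- write_dataset(ds, DATA_DIR)

counts <- as.data.frame(table(ds$labels$class_label))
names(counts) <- c("class_label", "n_drugs")
tsv(counts, file.path(RESULTS_DIR, "01_class_counts.tsv"))

rep <- validate_inputs(paths[["curves"]], paths[["labels"]])
print(rep)
stopifnot(rep$ok)
message("01_simulate: ", nrow(ds$curves), " curve rows written to ",
        DATA_DIR)
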