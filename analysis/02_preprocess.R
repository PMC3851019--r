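#!/usr/bin/env Rscript
# Stage 2 — curves to corpus.
#
# Normalizes every dose-response curve by its DMSO control (fold of
# control), integrates (ratio - 1) over log2(dose) to one AUC per
# (drug, endpoint, time point) — 40 values per drug — then discretizes
# each AUC column into 100 equal-width bins and reorients the table so
# each drug-hour is a document over the 10 endpoints.

source("analysis/00_common.R")

message("02_preprocess: building the AUC table and corpus")
curves <- read_curves(file.path(DATA_DIR, "curves.tsv"))
auc <- build_auc_table(curves)
write_auc_table(auc, file.path(MODEL_DIR, "auc_table.tsv"))
message("  AUC table: ", nrow(auc), " drugs x ", ncol(auc), " columns")

corp <- build_corpus(discretize(auc, n_bins = 100))
print(corp)
write_corpus(corp, file.path(RESULTS_DIR, "02_corpus.tsv"),
             file.path(MODEL_DIR, "corpus_triplets.tsv"))

len <- rowSums(corp$counts)
tsv(data.frame(
  n_documents = nrow(corp$counts), n_terms = ncol(corp$counts),
  n_tokens = sum(corp$counts),
  doc_length_min = min(len), doc_length_median = median(len),
  doc_length_max = max(len)),
  file.path(RESULTS_DIR, "02_corpus_summary.tsv"))
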