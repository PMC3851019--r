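#!/usr/bin/env Rscript
# Stage 4 — endpoint assignment and diagnostic topics.
#
# Assigns each endpoint to its most probable topic (disjoint groups),
# then scores S[c,k] = mu[c,k] / sum_c' mu[c',k] per class setting and
# HCS time point, and declares each class's argmax topic diagnostic —
# Table-3-style matrices for Settings I/II/III and the 3-class split.

source("analysis/00_common.R")

dt <- read.delim(file.path(MODEL_DIR, "doc_topic.tsv"))
doc_topic <- as.matrix(dt[, -1]); rownames(doc_topic) <- dt$doc_id
tw <- read.delim(file.path(MODEL_DIR, "topic_word.tsv"))
topic_word <- t(as.matrix(tw[, -1])); colnames(topic_word) <- tw$term_id

asn <- assign_endpoints(topic_word)
tsv(asn, file.path(RESULTS_DIR, "04_endpoint_assignment.tsv"))
message("04_diagnostics: endpoint groups by topic:")
for (k in sort(unique(asn$topic)))
  message("  topic ", k, ": ",
          paste(asn$endpoint_id[asn$topic == k], collapse = ", "))

labels <- read_labels(file.path(DATA_DIR, "labels.tsv"))
times <- sort(unique(as.numeric(sub("^.*@", "", rownames(doc_topic)))))
for (st in default_settings(labels)) {
  diags <- lapply(times, function(t)
    diagnostic_score_matrix(doc_topic, st, t))
  write_scores(diags, file.path(RESULTS_DIR,
                                sprintf("04_scores_%s.tsv", st$name)))
  message("  ", st$name, ": diagnostic topic per class at ",
          paste(times, collapse = "/"), " h = ",
          paste(vapply(diags, function(d)
    paste(d$diagnostic_topic$topic, collapse = ","), ""),
    collapse = " | "))
}
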