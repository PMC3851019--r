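#!/usr/bin/env Rscript
# Stage 5 — the transitive linkage report.
#
# Joins each class's diagnostic topic to that topic's endpoint set:
# the bridge from in vitro endpoint groups, through topics, to the
# in vivo necrosis classes.

source("analysis/00_common.R")

dt <- read.delim(file.path(MODEL_DIR, "doc_topic.tsv"))
doc_topic <- as.matrix(dt[, -1]); rownames(doc_topic) <- dt$doc_id
asn <- read.delim(file.path(RESULTS_DIR, "04_endpoint_assignment.tsv"))
labels <- read_labels(file.path(DATA_DIR, "labels.tsv"))

times <- sort(unique(as.numeric(sub("^.*@", "", rownames(doc_topic)))))
setting <- default_settings(labels)$three_class
diags <- lapply(times, function(t)
  diagnostic_score_matrix(doc_topic, setting, t))

rep <- bridge_report(asn, diags)
write_bridge_report(rep, file.path(RESULTS_DIR, "05_bridge_report.md"),
                    file.path(RESULTS_DIR, "05_bridge_report.json"))
message("05_report: linkage across time points")
print(rep$links[rep$links$time_h == 24, ])
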