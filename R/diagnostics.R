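#' Define a class setting over drugs
#'
#' A class setting partitions an evaluation set of drugs into C >= 2 (or,
#' degenerately, 1) labeled classes, mirroring the binary necrosis /
#' non-necrosis settings of the in vivo comparison (Setting I: necrosis at
#' 6 h vs not; Setting II: at 24 h vs not; Setting III: at either vs
#' neither) or the full three-class partition.
#'
#' @param name setting identifier.
#' @param assignment data frame with columns `drug_id`, `class_label`
#'   (each drug exactly once), or a named character vector
#'   (names = drug ids).
#' @param classes optional ordered class labels; defaults to order of first
#'   appearance.
#' @return An object of class `class_setting`.
#' @export
class_setting <- function(name, assignment, classes = NULL) {
  if (is.character(assignment) && !is.null(names(assignment))) {
    assignment <- data.frame(drug_id = names(assignment),
                             class_label = unname(assignment),
                             stringsAsFactors = FALSE)
  }
  if (!all(c("drug_id", "class_label") %in% names(assignment)))
    stop("assignment needs columns drug_id and class_label", call. = FALSE)
  if (anyDuplicated(assignment$drug_id))
    stop("each drug must have exactly one class label", call. = FALSE)
  if (is.null(classes)) classes <- unique(assignment$class_label)
  if (!all(assignment$class_label %in% classes))
    stop("assignment contains labels outside `classes`", call. = FALSE)
  n_per <- table(factor(assignment$class_label, levels = classes))
  if (any(n_per == 0))
    stop("every class must be non-empty; empty: ",
         paste(names(n_per)[n_per == 0], collapse = ", "), call. = FALSE)
  structure(list(name = name, assignment = assignment, classes = classes),
            class = "class_setting")
}

#' Build the three necrosis settings (plus the three-class partition)
#'
#' From disjoint drug labels `necrosis_6h` / `necrosis_24h` /
#' `non_necrosis`, constructs the evaluation settings of the in vivo
#' comparison: Setting I (necrosis at 6 h vs all others), Setting II
#' (necrosis at 24 h vs all others), Setting III (necrosis at either hour
#' vs never), and the full `three_class` setting.
#'
#' @param labels data frame with `drug_id`, `class_label`.
#' @return A named list of `class_setting` objects.
#' @export
default_settings <- function(labels) {
  lab <- labels$class_label
  mk <- function(nm, cls) {
    class_setting(nm, data.frame(drug_id = labels$drug_id, class_label = cls,
                                 stringsAsFactors = FALSE),
                  classes = unique(c("necrosis", "non_necrosis")[
                    c("necrosis", "non_necrosis") %in% cls]))
  }
  list(
    setting_I = mk("setting_I",
                   ifelse(lab == "necrosis_6h", "necrosis", "non_necrosis")),
    setting_II = mk("setting_II",
                    ifelse(lab == "necrosis_24h", "necrosis", "non_necrosis")),
    setting_III = mk("setting_III",
                     ifelse(lab %in% c("necrosis_6h", "necrosis_24h"),
                            "necrosis", "non_necrosis")),
    three_class = class_setting(
      "three_class",
      data.frame(drug_id = labels$drug_id, class_label = lab,
                 stringsAsFactors = FALSE),
      classes = intersect(c("necrosis_6h", "necrosis_24h", "non_necrosis"),
                          unique(lab)))
  )
}

doc_topic_of <- function(x) {
  if (inherits(x, "hcs_lda")) x$doc_topic else as.matrix(x)
}

# Split "drug@time" document ids.
parse_doc_ids <- function(ids) {
  parts <- strsplit(ids, "@", fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop("document ids must have the form drug_id@time_h", call. = FALSE)
  list(drug = vapply(parts, `[[`, "", 1),
       time = as.numeric(vapply(parts, `[[`, "", 2)))
}

#' Per-class mean topic probabilities at one HCS time point
#'
#' For each class c and topic k, the arithmetic mean of
#' p(topic k | document) over the setting's drugs, using the single
#' document each drug has at the requested HCS time point.
#'
#' @param doc_topic an `hcs_lda` or a documents x K probability matrix with
#'   `drug@time` row names.
#' @param setting a [class_setting()].
#' @param time_h HCS measurement time point (hours) selecting the
#'   documents.
#' @return A C x K numeric matrix with class labels as row names.
#' @export
class_means <- function(doc_topic, setting, time_h) {
  stopifnot(inherits(setting, "class_setting"))
  dt <- doc_topic_of(doc_topic)
  ids <- parse_doc_ids(rownames(dt))
  at_t <- ids$time == time_h
  drug_rows <- stats::setNames(which(at_t), ids$drug[at_t])
  missing <- setdiff(setting$assignment$drug_id, names(drug_rows))
  if (length(missing) > 0)
    stop(sprintf("labeled drug(s) with no document at %g h: %s", time_h,
                 paste(utils::head(missing, 5), collapse = ", ")),
         call. = FALSE)
  classes <- setting$classes
  mu <- matrix(NA_real_, length(classes), ncol(dt),
               dimnames = list(classes,
                               sprintf("topic_%d", seq_len(ncol(dt)))))
  for (ci in seq_along(classes)) {
    drugs <- setting$assignment$drug_id[
      setting$assignment$class_label == classes[ci]]
    mu[ci, ] <- colMeans(dt[drug_rows[drugs], , drop = FALSE])
  }
  mu
}

#' Diagnostic significance scores from class means
#'
#' Normalizes each topic column of the class-mean matrix over classes:
#' `S[c, k] = mu[c, k] / sum_c' mu[c', k]`, so for every topic the class
#' scores sum to 1 and a class with score near 1 "owns" that topic.
#'
#' @param means C x K matrix of non-negative class means with no all-zero
#'   topic column.
#' @return A C x K score matrix with the same dimnames.
#' @export
diagnostic_scores <- function(means) {
  m <- as.matrix(means)
  if (any(m < 0)) stop("class means must be non-negative", call. = FALSE)
  colsum <- colSums(m)
  if (any(colsum == 0))
    stop("degenerate topic column(s) with all-zero class means: ",
         paste(which(colsum == 0), collapse = ", "), call. = FALSE)
  sweep(m, 2, colsum, "/")
}

#' Diagnostic topic per class
#'
#' For each class, the topic with the maximal score; ties resolve to the
#' lowest topic index and are flagged rather than silently dropped
#' (near-0.5 scores in a two-class setting are uninformative).
#'
#' @param scores C x K score matrix from [diagnostic_scores()].
#' @return A data frame with columns `class_label`, `topic`, `score`,
#'   `tie`.
#' @export
diagnostic_topic <- function(scores) {
  s <- as.matrix(scores)
  k_star <- apply(s, 1, which.max)
  tie <- vapply(seq_len(nrow(s)), function(i)
    sum(s[i, ] == max(s[i, ])) > 1, logical(1))
  data.frame(
    class_label = rownames(s) %||% sprintf("class_%d", seq_len(nrow(s))),
    topic = as.integer(k_star),
    score = s[cbind(seq_len(nrow(s)), k_star)],
    tie = tie,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full diagnostic score matrix for one setting and time point
#'
#' Convenience wrapper: class means, scores and diagnostic topics in one
#' object.
#'
#' @inheritParams class_means
#' @return An object of class `diagnostic_score_matrix` with elements
#'   `setting`, `time_h`, `class_means`, `scores`, `diagnostic_topic`.
#' @export
diagnostic_score_matrix <- function(doc_topic, setting, time_h) {
  mu <- class_means(doc_topic, setting, time_h)
  s <- diagnostic_scores(mu)
  structure(
    list(setting = setting$name, time_h = time_h, class_means = mu,
         scores = s, diagnostic_topic = diagnostic_topic(s)),
    class = "diagnostic_score_matrix"
  )
}

#' @export
print.diagnostic_score_matrix <- function(x, ...) {
  cat(sprintf("<diagnostic_score_matrix> setting %s, %g h\n",
              x$setting, x$time_h))
  print(round(x$scores, 3))
  dg <- x$diagnostic_topic
  cat("diagnostic topics:",
      paste(sprintf("%s -> topic %d%s", dg$class_label, dg$topic,
                    ifelse(dg$tie, " (tie)", "")), collapse = ", "), "\n")
  invisible(x)
}

#' Assign each endpoint to its most probable topic
#'
#' Compares p(endpoint | topic) across the K topics for every endpoint and
#' assigns the endpoint to the argmax topic, producing the disjoint
#' endpoint groups; ties resolve to the lowest topic index and are flagged.
#'
#' @param topic_word an `hcs_lda` or a K x V probability matrix with term
#'   names as columns.
#' @return A data frame with columns `endpoint_id`, `topic`, `p`, `tie`.
#' @export
assign_endpoints <- function(topic_word) {
  tw <- if (inherits(topic_word, "hcs_lda")) topic_word$topic_word
        else as.matrix(topic_word)
  terms <- colnames(tw) %||% sprintf("term_%d", seq_len(ncol(tw)))
  k_star <- apply(tw, 2, which.max)
  tie <- vapply(seq_len(ncol(tw)), function(j)
    sum(tw[, j] == max(tw[, j])) > 1, logical(1))
  data.frame(
    endpoint_id = terms,
    topic = as.integer(k_star),
    p = tw[cbind(k_star, seq_len(ncol(tw)))],
    tie = tie,
    stringsAsFactors = FALSE
  )
}

#' Transitive in vitro -> topic -> in vivo linkage report
#'
#' Joins each class's diagnostic topic to that topic's endpoint set and
#' ranked term list, one section per setting and time point: the bridge
#' from in vitro endpoint groups, through topics, to in vivo
#' histopathology classes.
#'
#' @param assignment endpoint assignment from [assign_endpoints()].
#' @param diagnostics list of `diagnostic_score_matrix` objects (possibly
#'   empty).
#' @param model optional `hcs_lda` used to attach ranked term lists.
#' @return An object of class `bridge_report`: list with `assignment`,
#'   `topics` (endpoint sets and ranked terms per topic) and `links` (one
#'   row per setting x time point x class).
#' @export
bridge_report <- function(assignment, diagnostics = list(), model = NULL) {
  topics <- sort(unique(assignment$topic))
  topic_sets <- lapply(topics, function(k)
    assignment$endpoint_id[assignment$topic == k])
  names(topic_sets) <- sprintf("topic_%d", topics)
  ranked <- NULL
  if (!is.null(model)) {
    ranked <- lapply(seq_len(model$config$n_topics),
                     function(k) rank_terms(model, k))
    names(ranked) <- sprintf("topic_%d", seq_along(ranked))
  }
  links <- do.call(rbind, lapply(diagnostics, function(d) {
    dg <- d$diagnostic_topic
    data.frame(
      setting = d$setting, time_h = d$time_h,
      class_label = dg$class_label, topic = dg$topic, score = dg$score,
      tie = dg$tie,
      endpoints = vapply(dg$topic, function(k)
        paste(assignment$endpoint_id[assignment$topic == k],
              collapse = "; "), ""),
      stringsAsFactors = FALSE
    )
  }))
  structure(list(assignment = assignment, topics = topic_sets,
                 ranked_terms = ranked, links = links),
            class = "bridge_report")
}

#' @export
format.bridge_report <- function(x, ...) {
  out <- c("# Endpoint-topic-histopathology bridge report", "",
           "## Endpoint assignment", "")
  out <- c(out, sprintf("- %s -> topic %d (p = %.3f)%s",
                        x$assignment$endpoint_id, x$assignment$topic,
                        x$assignment$p,
                        ifelse(x$assignment$tie, " [tie]", "")))
  if (!is.null(x$links) && nrow(x$links) > 0) {
    for (st in unique(x$links$setting)) {
      sub <- x$links[x$links$setting == st, , drop = FALSE]
      for (t in unique(sub$time_h)) {
        out <- c(out, "", sprintf("## %s @ %g h", st, t), "")
        rows <- sub[sub$time_h == t, , drop = FALSE]
        out <- c(out, sprintf(
          "- class %s -> topic %d (S = %.3f)%s; endpoints: %s",
          rows$class_label, rows$topic, rows$score,
          ifelse(rows$tie, " [tie]", ""), rows$endpoints))
      }
    }
  }
  paste(out, collapse = "\n")
}

#' @export
print.bridge_report <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Write a bridge report to markdown and JSON
#'
#' @param report a `bridge_report`.
#' @param md_path,json_path output file paths (either may be NULL).
#' @return Invisibly, the paths written.
#' @export
write_bridge_report <- function(report, md_path = NULL, json_path = NULL) {
  if (!is.null(md_path)) writeLines(format(report), md_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(assignment = report$assignment, topics = report$topics,
           links = report$links),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(c(md_path, json_path))
}

#' Write diagnostic score matrices for one setting to TSV
#'
#' Rows are time point x class; columns the topic scores plus the
#' diagnostic topic and tie flag.
#'
#' @param diagnostics list of `diagnostic_score_matrix` objects for one
#'   setting (one per time point).
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_scores <- function(diagnostics, path) {
  df <- do.call(rbind, lapply(diagnostics, function(d) {
    s <- d$scores
    dg <- d$diagnostic_topic
    data.frame(time_h = d$time_h, class_label = rownames(s),
               s, diagnostic_topic = dg$topic, tie = dg$tie,
               check.names = FALSE, stringsAsFactors = FALSE)
  }))
  write_tsv_(df, path)
  invisible(path)
}
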