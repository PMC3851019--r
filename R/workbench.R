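#' Pipeline configuration
#'
#' Bundles all stage configurations for [run_pipeline()]. When `simulate`
#' is TRUE the synthetic generator writes its dataset into `input_dir`
#' first; otherwise `input_dir` must already contain `curves.tsv` and
#' `labels.tsv`.
#'
#' @param input_dir directory holding (or receiving) the input TSVs.
#' @param output_dir directory for all stage outputs; must differ from
#'   `input_dir`.
#' @param simulate whether to run the synthetic-data stage.
#' @param sim a [sim_config()].
#' @param endpoints endpoint catalog.
#' @param normalization,n_bins,binning preprocessing switches (see
#'   [build_auc_table()] and [discretize()]).
#' @param lda an [lda_config()]; its seed is overridden by a seed derived
#'   from `seed`.
#' @param seed single global integer seed; per-stage seeds are derived from
#'   it deterministically so stages can be re-run in isolation.
#' @param verbose print stage progress.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, output_dir, simulate = TRUE,
                            sim = sim_config(),
                            endpoints = default_endpoints(),
                            normalization = "ratio", n_bins = 100L,
                            binning = "equal_width",
                            lda = lda_config(), seed = 1L,
                            verbose = FALSE) {
  if (normalizePath(input_dir, mustWork = FALSE) ==
      normalizePath(output_dir, mustWork = FALSE))
    stop("output_dir must be distinct from input_dir", call. = FALSE)
  if (length(seed) != 1 || is.na(seed) || seed != as.integer(seed))
    stop("invalid pipeline config: field 'seed' must be a single integer",
         call. = FALSE)
  stopifnot(inherits(sim, "sim_config"), inherits(lda, "lda_config"))
  validate_endpoints(endpoints)
  structure(
    list(input_dir = input_dir, output_dir = output_dir,
         simulate = isTRUE(simulate), sim = sim, endpoints = endpoints,
         normalization = normalization, n_bins = as.integer(n_bins),
         binning = binning, lda = lda, seed = as.integer(seed),
         verbose = isTRUE(verbose)),
    class = "pipeline_config"
  )
}

# Deterministic per-stage seed from the global seed and the stage name,
# kept inside 32-bit integer range.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 10007 + h * 7919) %% 2147483647)
}

#' Run the end-to-end pipeline
#'
#' Executes simulate (optional) -> preprocess -> fit -> diagnose -> report,
#' writing every intermediate and final file under `output_dir` and
#' returning a manifest that records the configuration hash, per-stage
#' seeds and timings, and an MD5 checksum of every file written. Re-running
#' with the same configuration and seed reproduces byte-identical corpus,
#' CPT and score files.
#'
#' @param config a [pipeline_config()].
#' @return The manifest, invisibly also written to
#'   `output_dir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  say <- function(...) if (config$verbose) message(sprintf(...))
  stage_wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  timings <- list()
  clock <- function(stage, expr) {
    st <- Sys.time()
    res <- stage_wrap(stage, expr)
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), st, units = "secs"))
    res
  }

  curves_path <- file.path(config$input_dir, "curves.tsv")
  labels_path <- file.path(config$input_dir, "labels.tsv")
  if (!config$simulate &&
      (!file.exists(curves_path) || !file.exists(labels_path))) {
    stop("input error: curves.tsv / labels.tsv not found in ",
         config$input_dir, " and simulation is disabled", call. = FALSE)
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  stages <- character(0)
  if (config$simulate) {
    say("stage simulate")
    sim_cfg <- config$sim
    sim_cfg$seed <- derive_seed(config$seed, "simulate")
    clock("simulate", {
      ds <- generate_dataset(sim_cfg, config$endpoints)
      write_dataset(ds, config$input_dir)
    })
    stages <- c(stages, "simulate")
  }

  say("stage preprocess")
  corpus <- clock("preprocess", {
    curves <- read_curves(curves_path)
    tab <- build_auc_table(curves, config$endpoints, config$normalization)
    write_auc_table(tab, file.path(config$output_dir, "auc_table.tsv"))
    disc <- discretize(tab, n_bins = config$n_bins, scheme = config$binning)
    corp <- build_corpus(disc)
    write_corpus(corp, file.path(config$output_dir, "corpus.tsv"),
                 file.path(config$output_dir, "corpus_triplets.tsv"))
    corp
  })
  stages <- c(stages, "preprocess")

  say("stage fit")
  model <- clock("fit", {
    lda_cfg <- config$lda
    lda_cfg$seed <- derive_seed(config$seed, "fit")
    m <- fit_lda(corpus, lda_cfg)
    write_model(m, config$output_dir)
    m
  })
  stages <- c(stages, "fit")

  say("stage diagnose")
  diag_out <- clock("diagnose", {
    labels <- read_labels(labels_path)
    settings <- default_settings(labels)
    times <- sort(unique(corpus$doc_time))
    per_setting <- lapply(settings, function(st)
      lapply(times, function(t) diagnostic_score_matrix(model, st, t)))
    for (nm in names(per_setting)) {
      write_scores(per_setting[[nm]],
                   file.path(config$output_dir,
                             sprintf("scores_%s.tsv", nm)))
    }
    assignment <- assign_endpoints(model)
    write_tsv_(assignment, file.path(config$output_dir, "assignment.tsv"))
    list(settings = per_setting, assignment = assignment)
  })
  stages <- c(stages, "diagnose")

  say("stage report")
  clock("report", {
    rep <- bridge_report(diag_out$assignment,
                         unlist(diag_out$settings, recursive = FALSE),
                         model = model)
    write_bridge_report(rep,
                        file.path(config$output_dir, "bridge_report.md"),
                        file.path(config$output_dir, "bridge_report.json"))
  })
  stages <- c(stages, "report")

  outputs <- list.files(config$output_dir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  checksums <- tools::md5sum(outputs)
  names(checksums) <- basename(outputs)

  cfg_for_hash <- config
  cfg_for_hash$verbose <- NULL
  manifest <- list(
    config_hash = hash_object(cfg_for_hash),
    global_seed = config$seed,
    stage_seeds = list(simulate = derive_seed(config$seed, "simulate"),
                       fit = derive_seed(config$seed, "fit")),
    stages = stages,
    corpus = list(n_documents = nrow(corpus$counts),
                  n_terms = ncol(corpus$counts),
                  n_tokens = sum(corpus$counts)),
    timings_s = timings,
    files = as.list(checksums),
    total_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# MD5 hash of an R object via its serialization to a temp file.
hash_object <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(x, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' Validate input TSV files
#'
#' Schema checks for the curves and labels dialects: required columns,
#' duplicate keys, positive strictly-increasing doses within each curve,
#' and control coverage. Collects all problems rather than stopping at the
#' first.
#'
#' @param curves_path path to a curves TSV (or NULL to skip).
#' @param labels_path path to a labels TSV (or NULL to skip).
#' @return An object of class `validation_report`: list with `ok` and a
#'   character vector `errors`.
#' @export
validate_inputs <- function(curves_path = NULL, labels_path = NULL) {
  errors <- character(0)
  note <- function(msg) errors <<- c(errors, msg)

  if (!is.null(curves_path)) {
    if (!file.exists(curves_path)) {
      note(sprintf("curves: file not found: %s", curves_path))
    } else {
      df <- tryCatch(read_tsv_(curves_path), error = function(e) {
        note(sprintf("curves: unreadable: %s", conditionMessage(e)))
        NULL
      })
      if (!is.null(df)) {
        req <- c("drug_id", "endpoint_id", "plate", "time_h", "dose_uM",
                 "value", "is_control")
        miss <- setdiff(req, names(df))
        if (length(miss) > 0) {
          note(sprintf("curves: missing column(s): %s",
                       paste(miss, collapse = ", ")))
        } else {
          if (!all(df$is_control %in% c(0L, 1L)))
            note("curves: is_control must be 0 or 1")
          if (any(df$dose_uM <= 0))
            note("curves: doses must be positive")
          keys <- paste(df$drug_id, df$endpoint_id, df$time_h,
                        df$is_control, sep = "\r")
          for (k in unique(keys)) {
            d <- df$dose_uM[keys == k]
            if (is.unsorted(d, strictly = TRUE)) {
              parts <- strsplit(k, "\r")[[1]]
              note(sprintf(
                "curves: non-increasing dose series for drug %s, endpoint %s at %s h",
                parts[1], parts[2], parts[3]))
            }
          }
        }
      }
    }
  }

  if (!is.null(labels_path)) {
    if (!file.exists(labels_path)) {
      note(sprintf("labels: file not found: %s", labels_path))
    } else {
      df <- tryCatch(
        read_tsv_(labels_path),
        error = function(e) {
          note(sprintf("labels: unreadable: %s", conditionMessage(e)))
          NULL
        })
      if (!is.null(df)) {
        miss <- setdiff(c("drug_id", "class_label"), names(df))
        if (length(miss) > 0)
          note(sprintf("labels: missing column(s): %s",
                       paste(miss, collapse = ", ")))
        else if (anyDuplicated(df$drug_id))
          note(sprintf("labels: duplicated drug_id: %s",
                       paste(unique(df$drug_id[duplicated(df$drug_id)]),
                             collapse = ", ")))
      }
    }
  }

  structure(list(ok = length(errors) == 0, errors = errors),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$ok) cat("validation OK: no errors\n")
  else cat("validation FAILED:\n", paste("-", x$errors, collapse = "\n"),
           "\n")
  invisible(x)
}
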