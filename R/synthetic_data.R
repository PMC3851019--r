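#' Simulation configuration for the synthetic HCS generator
#'
#' Bundles and validates the knobs of the synthetic dose-response study.
#' Defaults reproduce the design of the screening campaign the pipeline
#' targets: 122 drugs, 4 measurement times (1, 6, 24, 48 h), a 10-point
#' 2-fold dilution series up to 200 uM, and three planted drug classes
#' (early necrosis, late necrosis, no necrosis) whose default proportions
#' 0.30 / 0.26 / 0.44 follow the 15 : 13 : 22 split of the in vivo
#' histopathology study that motivates the class labels.
#'
#' @param n_drugs number of treated compounds.
#' @param time_points_h ordered vector of HCS measurement times in hours.
#' @param n_doses number of dose levels per curve (>= 2).
#' @param max_dose_uM top concentration of the dilution series, in uM.
#' @param dilution_factor fold-dilution between consecutive doses (> 1).
#' @param class_fractions named proportions of the planted classes
#'   `necrosis_6h`, `necrosis_24h`, `non_necrosis`; must sum to 1.
#' @param effect_size mean activation shift of an "on" endpoint at the top
#'   dose, in control-normalized (fold-of-control minus one) units.
#' @param noise_sd standard deviation of Gaussian measurement noise on the
#'   control-normalized scale.
#' @param seed integer random seed; mandatory so every dataset is
#'   reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_drugs = 122L,
                       time_points_h = c(1, 6, 24, 48),
                       n_doses = 10L,
                       max_dose_uM = 200,
                       dilution_factor = 2,
                       class_fractions = c(necrosis_6h = 0.30,
                                           necrosis_24h = 0.26,
                                           non_necrosis = 0.44),
                       effect_size = 1.0,
                       noise_sd = 0.05,
                       seed = 1L) {
  fail <- function(field, msg) {
    stop(sprintf("invalid simulation config: field '%s' %s", field, msg),
         call. = FALSE)
  }
  if (length(n_drugs) != 1 || n_drugs < 1 || n_drugs != as.integer(n_drugs))
    fail("n_drugs", "must be a positive integer")
  if (length(time_points_h) < 1 || any(time_points_h <= 0) ||
      is.unsorted(time_points_h, strictly = TRUE))
    fail("time_points_h", "must be strictly increasing positive hours")
  if (length(n_doses) != 1 || n_doses < 2)
    fail("n_doses", "must be >= 2")
  if (max_dose_uM <= 0) fail("max_dose_uM", "must be positive")
  if (dilution_factor <= 1) fail("dilution_factor", "must be > 1")
  if (is.null(names(class_fractions)) || any(!nzchar(names(class_fractions))))
    fail("class_fractions", "must be a named vector")
  if (any(class_fractions < 0))
    fail("class_fractions", "must be non-negative")
  if (abs(sum(class_fractions) - 1) > 1e-9)
    fail("class_fractions", "must sum to 1 (tolerance 1e-9)")
  if (effect_size < 0) fail("effect_size", "must be >= 0")
  if (noise_sd < 0) fail("noise_sd", "must be >= 0")
  if (length(seed) != 1 || is.na(seed) || seed != as.integer(seed))
    fail("seed", "must be a single integer")

  structure(
    list(
      n_drugs = as.integer(n_drugs),
      time_points_h = as.numeric(time_points_h),
      n_doses = as.integer(n_doses),
      max_dose_uM = as.numeric(max_dose_uM),
      dilution_factor = as.numeric(dilution_factor),
      class_fractions = class_fractions,
      effect_size = as.numeric(effect_size),
      noise_sd = as.numeric(noise_sd),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Largest-remainder apportionment of n items over fractions; deterministic
# (ties broken by earlier class) so label counts never wobble with the seed.
largest_remainder <- function(n, fractions) {
  exact <- n * fractions
  counts <- floor(exact)
  short <- n - sum(counts)
  if (short > 0) {
    rem <- exact - counts
    take <- order(-rem, seq_along(rem))[seq_len(short)]
    counts[take] <- counts[take] + 1
  }
  stats::setNames(as.integer(counts), names(fractions))
}

# Run expr with a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Per-class activation schedule over event groups: which latent group a
# planted class switches on at each measurement time, and how strongly
# (as a multiple of effect_size).
default_schedule <- function(time_points_h) {
  nt <- length(time_points_h)
  ramp <- seq(0.25, 1, length.out = nt)   # late necrosis grows over time
  rbind(
    data.frame(class_label = "necrosis_6h", time_h = time_points_h,
               active_groups = "1", activation = 1.0),
    data.frame(class_label = "necrosis_24h", time_h = time_points_h,
               active_groups = "2", activation = ramp),
    data.frame(class_label = "non_necrosis", time_h = time_points_h,
               active_groups = "3", activation = 0.5)
  )
}

#' Generate a synthetic HCS dose-response dataset
#'
#' Produces well-level dose-response curves for every (drug, endpoint, time
#' point) plus one shared DMSO control curve per (endpoint, time point),
#' with planted latent structure: each drug belongs to one of three classes,
#' and each class switches on one event group of endpoints according to a
#' documented schedule — early-necrosis drugs activate group 1 strongly from
#' the first hour, late-necrosis drugs activate group 2 with magnitude
#' ramping up over time, and non-necrosis drugs activate group 3 mildly
#' throughout. An "on" endpoint follows a monotone sigmoidal dose-response
#' around the control baseline reaching a fold-change shift of
#' `effect_size * activation` at the top dose; an "off" endpoint equals the
#' control baseline plus noise.
#'
#' @param config a [sim_config()].
#' @param endpoints endpoint catalog (see [default_endpoints()]).
#' @return An object of class `hcs_dataset`: a list with elements `curves`
#'   (long data frame: drug_id, endpoint_id, plate, time_h, dose_uM, value,
#'   is_control), `labels` (drug_id, class_label), `truth` (list with
#'   `endpoint_groups` and `schedule` data frames) and `config`.
#' @export
#' @examples
#' ds <- generate_dataset(sim_config(n_drugs = 4, seed = 1))
#' table(ds$labels$class_label)
generate_dataset <- function(config = sim_config(),
                             endpoints = default_endpoints()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_endpoints(endpoints)
  if (length(unique(endpoints$event_group)) < 2)
    stop("planting latent structure needs at least 2 event groups",
         call. = FALSE)
  ngrp <- max(endpoints$event_group)

  doses <- config$max_dose_uM *
    config$dilution_factor^(-(config$n_doses - 1):0)
  ld <- log2(doses)
  mid <- (ld[1] + ld[length(ld)]) / 2
  sig <- stats::plogis(ld - mid)
  sig <- sig / sig[length(sig)]        # exactly 1 at the top dose

  schedule <- default_schedule(config$time_points_h)
  classes <- names(config$class_fractions)
  if (!all(unique(schedule$class_label) %in% classes)) {
    stop("class_fractions names must cover the activation schedule classes",
         call. = FALSE)
  }
  counts <- largest_remainder(config$n_drugs, config$class_fractions)
  drug_ids <- sprintf("drug_%03d", seq_len(config$n_drugs))

  with_seed(config$seed, {
    class_vec <- sample(rep(classes, counts))
    labels <- data.frame(drug_id = drug_ids, class_label = class_vec,
                         stringsAsFactors = FALSE)

    nt <- length(config$time_points_h)
    nd <- config$n_doses
    ne <- nrow(endpoints)
    baseline <- 100  # arbitrary raw assay units; cancels in normalization

    # schedule lookup: activation multiplier per (class, time, group)
    act <- array(0, dim = c(length(classes), nt, ngrp),
                 dimnames = list(classes, NULL, NULL))
    for (i in seq_len(nrow(schedule))) {
      ti <- match(schedule$time_h[i], config$time_points_h)
      grps <- as.integer(strsplit(schedule$active_groups[i], ",")[[1]])
      act[schedule$class_label[i], ti, grps] <- schedule$activation[i]
    }

    # treatment grid: drug x endpoint x time x dose, drug-major ordering
    grid <- expand.grid(dose_i = seq_len(nd), time_i = seq_len(nt),
                        ep_i = seq_len(ne), drug_i = seq_len(config$n_drugs))
    cls_i <- match(class_vec[grid$drug_i], classes)
    grp <- endpoints$event_group[grid$ep_i]
    activation <- act[cbind(cls_i, grid$time_i, grp)]
    shift <- config$effect_size * activation * sig[grid$dose_i]
    value <- baseline * (1 + shift +
                           stats::rnorm(nrow(grid), sd = config$noise_sd))
    curves <- data.frame(
      drug_id = drug_ids[grid$drug_i],
      endpoint_id = endpoints$name[grid$ep_i],
      plate = endpoints$plate[grid$ep_i],
      time_h = config$time_points_h[grid$time_i],
      dose_uM = doses[grid$dose_i],
      value = value,
      is_control = 0L,
      stringsAsFactors = FALSE
    )

    cgrid <- expand.grid(dose_i = seq_len(nd), time_i = seq_len(nt),
                         ep_i = seq_len(ne))
    cvalue <- baseline * (1 + stats::rnorm(nrow(cgrid), sd = config$noise_sd))
    controls <- data.frame(
      drug_id = "DMSO",
      endpoint_id = endpoints$name[cgrid$ep_i],
      plate = endpoints$plate[cgrid$ep_i],
      time_h = config$time_points_h[cgrid$time_i],
      dose_uM = doses[cgrid$dose_i],
      value = cvalue,
      is_control = 1L,
      stringsAsFactors = FALSE
    )

    structure(
      list(
        curves = rbind(curves, controls),
        labels = labels,
        truth = list(
          endpoint_groups = data.frame(
            endpoint_id = endpoints$name,
            event_group = endpoints$event_group,
            stringsAsFactors = FALSE
          ),
          schedule = schedule
        ),
        config = config
      ),
      class = "hcs_dataset"
    )
  })
}

#' @export
print.hcs_dataset <- function(x, ...) {
  cat(sprintf(
    "<hcs_dataset> %d drugs, %d endpoints, %d time points, %d dose levels\n",
    x$config$n_drugs, length(unique(x$curves$endpoint_id)),
    length(x$config$time_points_h), x$config$n_doses))
  cat("  classes:", paste(sprintf("%s=%d", names(table(x$labels$class_label)),
                                  table(x$labels$class_label)),
                          collapse = ", "), "\n")
  invisible(x)
}

write_tsv_ <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

read_tsv_ <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a synthetic dataset to TSV files
#'
#' Writes `curves.tsv`, `labels.tsv`, `truth_endpoints.tsv` and
#' `truth_schedule.tsv` into `directory` in the dialects the preprocessing
#' readers consume; the round trip through [read_dataset()] reproduces the
#' dataset.
#'
#' @param dataset an `hcs_dataset`.
#' @param directory output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_dataset <- function(dataset, directory) {
  if (!inherits(dataset, "hcs_dataset"))
    stop("dataset must be an hcs_dataset", call. = FALSE)
  if (nrow(dataset$curves) == 0 || nrow(dataset$labels) == 0)
    stop("refusing to write an empty dataset", call. = FALSE)
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    curves = file.path(directory, "curves.tsv"),
    labels = file.path(directory, "labels.tsv"),
    truth_endpoints = file.path(directory, "truth_endpoints.tsv"),
    truth_schedule = file.path(directory, "truth_schedule.tsv")
  )
  write_tsv_(dataset$curves, paths["curves"])
  write_tsv_(dataset$labels, paths["labels"])
  write_tsv_(dataset$truth$endpoint_groups, paths["truth_endpoints"])
  write_tsv_(dataset$truth$schedule, paths["truth_schedule"])
  invisible(paths)
}

#' Read back a dataset written by [write_dataset()]
#'
#' @param directory directory containing the TSV files.
#' @return An `hcs_dataset` (without the original `config`).
#' @export
read_dataset <- function(directory) {
  curves <- read_curves(file.path(directory, "curves.tsv"))
  labels <- read_labels(file.path(directory, "labels.tsv"))
  structure(
    list(
      curves = curves,
      labels = labels,
      truth = local({
        sched <- read_tsv_(file.path(directory, "truth_schedule.tsv"))
        sched$active_groups <- as.character(sched$active_groups)
        list(
          endpoint_groups = read_tsv_(file.path(directory,
                                                "truth_endpoints.tsv")),
          schedule = sched
        )
      }),
      config = NULL
    ),
    class = "hcs_dataset"
  )
}

#' Read a curves TSV
#'
#' Expects columns drug_id, endpoint_id, plate, time_h, dose_uM, value,
#' is_control (0/1), one row per dose level.
#'
#' @param path file path.
#' @return A data frame of curves in long format.
#' @export
read_curves <- function(path) {
  df <- read_tsv_(path)
  required <- c("drug_id", "endpoint_id", "plate", "time_h", "dose_uM",
                "value", "is_control")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("curves file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

#' Read a labels TSV (drug_id, class_label)
#'
#' @param path file path.
#' @return A data frame with columns drug_id and class_label.
#' @export
read_labels <- function(path) {
  df <- read_tsv_(path)
  missing <- setdiff(c("drug_id", "class_label"), names(df))
  if (length(missing) > 0)
    stop("labels file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$drug_id))
    stop("labels file ", path, " has duplicated drug_id values",
         call. = FALSE)
  df
}
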