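#' Construct a dose-response curve
#'
#' @param doses strictly increasing positive concentrations (uM).
#' @param values measurements aligned to `doses`.
#' @param drug_id,endpoint_id,time_h identity of the curve.
#' @param baseline the no-effect level on the curve's value scale: 1 for
#'   fold-of-control (ratio-normalized) curves, 0 for difference-normalized
#'   curves. The AUC integrates `values - baseline`.
#' @return An object of class `dose_response_curve`.
#' @export
dose_response_curve <- function(doses, values, drug_id = NA_character_,
                                endpoint_id = NA_character_,
                                time_h = NA_real_, baseline = 1) {
  if (length(doses) != length(values))
    stop("doses and values must have equal length", call. = FALSE)
  if (length(doses) < 2)
    stop("insufficient data: a dose-response curve needs at least 2 doses",
         call. = FALSE)
  if (any(doses <= 0))
    stop("all doses must be positive (log-dose is taken)", call. = FALSE)
  if (is.unsorted(doses, strictly = TRUE))
    stop("doses must be strictly increasing", call. = FALSE)
  structure(
    list(drug_id = drug_id, endpoint_id = endpoint_id, time_h = time_h,
         doses = as.numeric(doses), values = as.numeric(values),
         baseline = baseline),
    class = "dose_response_curve"
  )
}

#' Normalize a treatment curve by its DMSO control curve
#'
#' Divides (default) or subtracts the vehicle-control curve measured for the
#' same endpoint and time point on an identical dose grid. Ratio
#' normalization yields fold-of-control values with a no-effect baseline of
#' 1; difference normalization yields deviations with baseline 0.
#'
#' @param treatment,control `dose_response_curve` objects on identical dose
#'   grids.
#' @param method `"ratio"` (fold of control, the HCS convention) or
#'   `"difference"`.
#' @return The normalized `dose_response_curve` (treatment identity kept).
#' @export
#' @examples
#' trt <- dose_response_curve(c(100, 200), c(1, 1.5))
#' ctl <- dose_response_curve(c(100, 200), c(1, 1))
#' normalize_by_control(trt, ctl)$values  # 1.0 1.5
normalize_by_control <- function(treatment, control,
                                 method = c("ratio", "difference")) {
  method <- match.arg(method)
  stopifnot(inherits(treatment, "dose_response_curve"),
            inherits(control, "dose_response_curve"))
  if (length(treatment$doses) != length(control$doses) ||
      !isTRUE(all.equal(treatment$doses, control$doses))) {
    stop(sprintf(
      "dose grid mismatch between treatment (%s) and control curves",
      paste0(treatment$drug_id, "/", treatment$endpoint_id)),
      call. = FALSE)
  }
  if (method == "ratio") {
    zero <- which(control$values == 0)
    if (length(zero) > 0) {
      stop(sprintf(
        "division by zero control value at dose %g uM (endpoint %s, %s h)",
        control$doses[zero[1]], control$endpoint_id, control$time_h),
        call. = FALSE)
    }
    vals <- treatment$values / control$values
    baseline <- 1
  } else {
    vals <- treatment$values - control$values
    baseline <- 0
  }
  dose_response_curve(treatment$doses, vals, treatment$drug_id,
                      treatment$endpoint_id, treatment$time_h,
                      baseline = baseline)
}

#' Area under a control-normalized dose-response curve
#'
#' Trapezoidal integral of (value - baseline) over log2(dose). On a 2-fold
#' dilution series the log2 grid is uniform; integrating the deviation from
#' baseline makes a no-effect curve score exactly 0, and the log scale makes
#' the AUC invariant to relabeling the dose units.
#'
#' @param curve a normalized `dose_response_curve`.
#' @return A single dimensionless AUC value.
#' @export
#' @examples
#' crv <- dose_response_curve(c(100, 200), c(1, 3))
#' compute_auc(crv)  # trapezoid: (0 + 2)/2 * 1 log2-unit = 1
compute_auc <- function(curve) {
  stopifnot(inherits(curve, "dose_response_curve"))
  if (length(curve$doses) < 2)
    stop("insufficient data: AUC needs at least 2 dose points",
         call. = FALSE)
  pracma::trapz(log2(curve$doses), curve$values - curve$baseline)
}

#' Build the drug x (endpoint, time) AUC table
#'
#' Normalizes each treatment curve by the control curve of its (endpoint,
#' time point) and integrates it. With the default 10-endpoint catalog and
#' 4 time points this yields 40 control-normalized AUC values per drug.
#' Columns are ordered time-major, then by endpoint catalog order, and named
#' `endpoint@time`.
#'
#' @param curves long-format curves data frame (treatment and control rows;
#'   see [read_curves()]), or an `hcs_dataset`.
#' @param endpoints endpoint catalog fixing the column order.
#' @param normalization `"ratio"` or `"difference"`.
#' @return A numeric matrix of class `auc_table` (drugs x endpoint-time),
#'   with drug ids as row names.
#' @export
build_auc_table <- function(curves, endpoints = default_endpoints(),
                            normalization = c("ratio", "difference")) {
  normalization <- match.arg(normalization)
  if (inherits(curves, "hcs_dataset")) curves <- curves$curves
  validate_endpoints(endpoints)

  trt <- curves[curves$is_control == 0, , drop = FALSE]
  ctl <- curves[curves$is_control == 1, , drop = FALSE]
  if (nrow(trt) == 0) stop("no treatment curves in input", call. = FALSE)
  if (nrow(ctl) == 0) stop("no control curves in input", call. = FALSE)

  drugs <- unique(trt$drug_id)
  times <- sort(unique(trt$time_h))
  eps <- endpoints$name
  unknown <- setdiff(unique(trt$endpoint_id), eps)
  if (length(unknown) > 0)
    stop("curves contain endpoint(s) absent from the catalog: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  key <- function(d, e, t) paste(d, e, t, sep = "\r")
  trt_split <- split(seq_len(nrow(trt)), key(trt$drug_id, trt$endpoint_id,
                                             trt$time_h))
  ctl_split <- split(seq_len(nrow(ctl)), paste(ctl$endpoint_id, ctl$time_h,
                                               sep = "\r"))

  # completeness check before any computation
  want <- expand.grid(e = eps, t = times, d = drugs, stringsAsFactors = FALSE)
  want_keys <- key(want$d, want$e, want$t)
  gaps <- want_keys[!(want_keys %in% names(trt_split))]
  if (length(gaps) > 0) {
    shown <- gsub("\r", " / ", utils::head(gaps, 5))
    stop(sprintf("incomplete curve set: missing %d (drug, endpoint, time) %s: %s",
                 length(gaps),
                 if (length(gaps) == 1) "combination" else "combinations",
                 paste(shown, collapse = "; ")), call. = FALSE)
  }
  ctl_want <- paste(rep(eps, times = length(times)),
                    rep(times, each = length(eps)), sep = "\r")
  ctl_gaps <- unique(ctl_want[!(ctl_want %in% names(ctl_split))])
  if (length(ctl_gaps) > 0) {
    stop("missing control curve(s) for: ",
         paste(gsub("\r", " @ ", utils::head(ctl_gaps, 5)), collapse = "; "),
         call. = FALSE)
  }

  ctl_curves <- lapply(ctl_split, function(idx) {
    o <- idx[order(ctl$dose_uM[idx])]
    dose_response_curve(ctl$dose_uM[o], ctl$value[o],
                        drug_id = "control",
                        endpoint_id = ctl$endpoint_id[o[1]],
                        time_h = ctl$time_h[o[1]])
  })

  n_col <- length(times) * length(eps)
  tab <- matrix(NA_real_, nrow = length(drugs), ncol = n_col,
                dimnames = list(
                  drugs,
                  paste0(rep(eps, times = length(times)), "@",
                         rep(times, each = length(eps)))))
  col_of <- function(ti, ei) (ti - 1L) * length(eps) + ei
  for (di in seq_along(drugs)) {
    for (ti in seq_along(times)) {
      for (ei in seq_along(eps)) {
        idx <- trt_split[[key(drugs[di], eps[ei], times[ti])]]
        o <- idx[order(trt$dose_uM[idx])]
        tcurve <- dose_response_curve(trt$dose_uM[o], trt$value[o],
                                      drug_id = drugs[di],
                                      endpoint_id = eps[ei],
                                      time_h = times[ti])
        ccurve <- ctl_curves[[paste(eps[ei], times[ti], sep = "\r")]]
        norm <- normalize_by_control(tcurve, ccurve, method = normalization)
        tab[di, col_of(ti, ei)] <- compute_auc(norm)
      }
    }
  }
  structure(tab, class = c("auc_table", class(tab)),
            times = times, endpoints = eps)
}

#' Discretize an AUC table into integer bins
#'
#' Per column, the value range `[min, max]` is divided into `n_bins`
#' equal-width bins and every entry is replaced by its 1-based bin index;
#' the column maximum maps to `n_bins` and a constant column maps entirely
#' to bin 1 (no information, minimal token weight). The 1-based convention
#' guarantees every endpoint contributes at least one token to every
#' document, keeping the topic model's support fixed. Equal-frequency
#' binning (empirical-CDF ranks) is available for sensitivity analysis.
#'
#' @param table an `auc_table` (or plain numeric matrix).
#' @param n_bins number of bins (>= 2); the default follows the 100-bin
#'   discretization convention.
#' @param scheme `"equal_width"` (default) or `"equal_frequency"`.
#' @return An integer matrix of the same shape with entries in
#'   `1..n_bins`; attribute `n_bins` records the setting.
#' @export
#' @examples
#' discretize(matrix(c(0, 50, 100), ncol = 1), n_bins = 100)  # 1, 51, 100
discretize <- function(table, n_bins = 100L,
                       scheme = c("equal_width", "equal_frequency")) {
  scheme <- match.arg(scheme)
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  m <- unclass(table)
  if (!is.matrix(m)) m <- as.matrix(m)
  if (any(!is.finite(m)))
    stop("AUC table contains non-finite entries; cannot discretize",
         call. = FALSE)
  out <- m
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    if (scheme == "equal_width") {
      rng <- range(v)
      if (rng[2] - rng[1] == 0) {
        out[, j] <- 1L
      } else {
        width <- (rng[2] - rng[1]) / n_bins
        out[, j] <- pmin(floor((v - rng[1]) / width) + 1L, n_bins)
      }
    } else {
      out[, j] <- ceiling(stats::ecdf(v)(v) * n_bins)
    }
  }
  storage.mode(out) <- "integer"
  structure(out, n_bins = as.integer(n_bins),
            times = attr(table, "times"), endpoints = attr(table, "endpoints"))
}

#' Reshape the discretized table into a drug-hour document corpus
#'
#' Reorients the drug x (endpoint, time) integer matrix so that each
#' (drug, time point) pair becomes one document and each endpoint becomes
#' one term; the bin index plays the role of a word count, so each document
#' row quantifies how strongly every endpoint responded for that drug at
#' that hour. Documents are ordered drug-major, then time ascending; terms
#' follow the endpoint catalog order. Document ids are `drug_id@time_h`.
#'
#' @param discrete_table integer matrix from [discretize()] with
#'   `endpoint@time` column names.
#' @return An object of class `hcs_corpus`: list with `counts` (documents x
#'   terms integer matrix), `doc_ids`, `term_ids`, `doc_drug`, `doc_time`.
#' @export
build_corpus <- function(discrete_table) {
  m <- discrete_table
  if (!is.matrix(m) || !is.integer(m))
    stop("build_corpus expects the integer matrix produced by discretize()",
         call. = FALSE)
  parts <- strsplit(colnames(m), "@", fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop("column names must have the form endpoint@time", call. = FALSE)
  col_ep <- vapply(parts, `[[`, "", 1)
  col_time <- as.numeric(vapply(parts, `[[`, "", 2))
  eps <- attr(m, "endpoints")
  if (is.null(eps)) eps <- unique(col_ep)
  times <- attr(m, "times")
  if (is.null(times)) times <- sort(unique(col_time))

  drugs <- rownames(m)
  nd <- length(drugs); nt <- length(times); ne <- length(eps)
  counts <- matrix(0L, nrow = nd * nt, ncol = ne,
                   dimnames = list(NULL, eps))
  doc_drug <- rep(drugs, each = nt)
  doc_time <- rep(times, times = nd)
  doc_ids <- paste0(doc_drug, "@", doc_time)
  rownames(counts) <- doc_ids
  for (ti in seq_len(nt)) {
    for (ei in seq_len(ne)) {
      j <- which(col_ep == eps[ei] & col_time == times[ti])
      if (length(j) != 1)
        stop(sprintf("expected exactly one column for %s@%s, found %d",
                     eps[ei], times[ti], length(j)), call. = FALSE)
      counts[(seq_len(nd) - 1L) * nt + ti, ei] <- m[, j]
    }
  }
  structure(
    list(counts = counts, doc_ids = doc_ids, term_ids = eps,
         doc_drug = doc_drug, doc_time = doc_time),
    class = "hcs_corpus"
  )
}

#' @export
print.hcs_corpus <- function(x, ...) {
  cat(sprintf("<hcs_corpus> %d documents x %d terms, %d tokens total\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' One-call preprocessing: curves to corpus
#'
#' @inheritParams build_auc_table
#' @inheritParams discretize
#' @return An `hcs_corpus`.
#' @export
preprocess_curves <- function(curves, endpoints = default_endpoints(),
                              normalization = "ratio", n_bins = 100L,
                              scheme = "equal_width") {
  tab <- build_auc_table(curves, endpoints, normalization)
  build_corpus(discretize(tab, n_bins = n_bins, scheme = scheme))
}

#' Write / read a corpus as TSV
#'
#' `write_corpus()` writes `corpus.tsv` (doc_id plus one integer column per
#' endpoint) and a sparse 1-based triplet file `corpus_triplets.tsv`
#' (header line with dimensions, then doc index, term index, count).
#'
#' @param corpus an `hcs_corpus`.
#' @param path output path for the dense TSV.
#' @param triplet_path optional output path for the sparse triplet file.
#' @return Invisibly, the path(s) written.
#' @export
write_corpus <- function(corpus, path, triplet_path = NULL) {
  df <- data.frame(doc_id = corpus$doc_ids, corpus$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_(df, path)
  if (!is.null(triplet_path)) {
    con <- file(triplet_path, "w")
    on.exit(close(con))
    writeLines(sprintf("%%dims\t%d\t%d", nrow(corpus$counts),
                       ncol(corpus$counts)), con)
    idx <- which(corpus$counts > 0, arr.ind = TRUE)
    writeLines(sprintf("%d\t%d\t%d", idx[, 1], idx[, 2],
                       corpus$counts[idx]), con)
  }
  invisible(c(path, triplet_path))
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  df <- read_tsv_(path)
  if (names(df)[1] != "doc_id")
    stop("corpus file must start with a doc_id column", call. = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$doc_id
  parts <- strsplit(df$doc_id, "@", fixed = TRUE)
  structure(
    list(counts = counts, doc_ids = df$doc_id,
         term_ids = colnames(counts),
         doc_drug = vapply(parts, `[[`, "", 1),
         doc_time = as.numeric(vapply(parts, `[[`, "", 2))),
    class = "hcs_corpus"
  )
}

#' Write / read an AUC table TSV (drug_id plus one column per endpoint@time)
#'
#' @param table an `auc_table`.
#' @param path file path.
#' @return Invisibly, `path` (write) or the `auc_table` (read).
#' @export
write_auc_table <- function(table, path) {
  df <- data.frame(drug_id = rownames(table), unclass(table),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_(df, path)
  invisible(path)
}

#' @rdname write_auc_table
#' @export
read_auc_table <- function(path) {
  df <- read_tsv_(path)
  if (names(df)[1] != "drug_id")
    stop("AUC table file must start with a drug_id column", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$drug_id
  parts <- strsplit(colnames(m), "@", fixed = TRUE)
  times <- sort(unique(as.numeric(vapply(parts, `[[`, "", 2))))
  eps <- unique(vapply(parts, `[[`, "", 1))
  structure(m, class = c("auc_table", class(m)), times = times,
            endpoints = eps)
}
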