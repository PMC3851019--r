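#' Default HCS endpoint catalog
#'
#' The ten-endpoint vocabulary of the CellCiphr-style rat hepatocyte panel:
#' eight distinct cellular endpoints measured on two plates, with Cell Loss
#' and Nuclear Size measured on both plates and treated as separate endpoints
#' (distinguished by a plate index in parentheses). Each endpoint carries a
#' planted latent event-group index used as ground truth by the synthetic
#' data generator and the recovery tests:
#'
#' * group 1 — severe-damage endpoints (Steatosis, DNA Fragmentation,
#'   Mitochondrial Potential, Lysosome Mass),
#' * group 2 — DNA Damage and Apoptosis,
#' * group 3 — Cell Loss and Nuclear Size on both plates.
#'
#' The row order of this catalog is the canonical term order used everywhere
#' downstream (AUC table columns, corpus terms, topic-word tables).
#'
#' @return A data frame with columns `name`, `plate` (1 or 2) and
#'   `event_group` (integer in 1..3).
#' @export
#' @examples
#' default_endpoints()
default_endpoints <- function() {
  data.frame(
    name = c(
      "Cell Loss (1)", "Nuclear Size (1)", "DNA Damage", "Apoptosis",
      "Lysosome Mass", "DNA Fragmentation",
      "Cell Loss (2)", "Nuclear Size (2)", "Mitochondrial Potential",
      "Steatosis"
    ),
    plate = c(1L, 1L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L),
    event_group = c(3L, 3L, 2L, 2L, 1L, 1L, 3L, 3L, 1L, 1L),
    stringsAsFactors = FALSE
  )
}

#' Validate an endpoint catalog
#'
#' @param endpoints data frame with columns `name`, `plate`, `event_group`.
#' @return The catalog, invisibly, after validation.
#' @keywords internal
validate_endpoints <- function(endpoints) {
  required <- c("name", "plate", "event_group")
  missing <- setdiff(required, names(endpoints))
  if (length(missing) > 0) {
    stop("endpoint catalog is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(endpoints) < 1) {
    stop("endpoint catalog is empty", call. = FALSE)
  }
  if (anyDuplicated(endpoints$name)) {
    stop("endpoint catalog has duplicated names", call. = FALSE)
  }
  g <- endpoints$event_group
  if (any(g != as.integer(g)) || any(g < 1L)) {
    stop("event_group must be positive integers", call. = FALSE)
  }
  if (!all(endpoints$plate %in% c(1L, 2L))) {
    stop("plate must be 1 or 2", call. = FALSE)
  }
  invisible(endpoints)
}
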