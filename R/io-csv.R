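#' Read events from a CSV file
#'
#' Expects a header row containing every panel marker; extra columns (e.g. a
#' `Time` channel) are dropped with a warning. Values must be numeric.
#'
#' @inheritParams read_fcs
#' @param path Path to a CSV with one row per event.
#' @return An [event_table()] with `transformed = FALSE`.
#' @export
read_events_csv <- function(path, panel, sample_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  panel <- marker_panel(panel)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty event table in ", path, call. = FALSE)
  missing <- setdiff(unclass(panel), names(df))
  if (length(missing)) {
    stop("CSV ", path, " is missing panel marker(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(df), unclass(panel))
  if (length(extra)) {
    warning("ignoring non-panel column(s) in ", basename(path), ": ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  df <- df[, unclass(panel), drop = FALSE]
  if (!all(vapply(df, is.numeric, logical(1)))) {
    bad <- names(df)[!vapply(df, is.numeric, logical(1))]
    stop("non-numeric values in column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  mat <- as.matrix(df)
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  event_table(mat, sample_id = sample_id, transformed = FALSE)
}

#' Read sample metadata
#'
#' @param path CSV with columns `sample_id` and `condition`.
#' @return A data frame with character columns `sample_id` and `condition`.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!all(c("sample_id", "condition") %in% names(df))) {
    stop("metadata CSV needs columns sample_id and condition", call. = FALSE)
  }
  df[, c("sample_id", "condition")]
}

#' Define a threshold gate on one marker
#'
#' @param marker Marker name, must belong to the panel.
#' @param direction `"positive"` keeps events strictly above the threshold,
#'   `"negative"` keeps events at or below it.
#' @param threshold Finite cutoff on the transformed intensity scale.
#' @return An object of class `gate_rule`.
#' @export
gate_rule <- function(marker, direction = c("positive", "negative"), threshold) {
  direction <- match.arg(direction)
  stopifnot(is.character(marker), length(marker) == 1L,
            is.numeric(threshold), length(threshold) == 1L, is.finite(threshold))
  structure(list(marker = marker, direction = direction, threshold = threshold),
            class = "gate_rule")
}

#' Apply rectangular threshold gates to an event table
#'
#' Keeps only events satisfying every rule (logical AND), e.g. CD45- CD31-
#' Sca-1+ PDGFRa+ to select the mesenchymal stromal compartment from ungated
#' stroma. Thresholds are interpreted on the transformed scale, so the table
#' must already be transformed. Gating is optional: the pipeline default is to
#' analyse all events, assuming instrument-side pre-gating.
#'
#' @param table A transformed [event_table()].
#' @param rules List of [gate_rule()] objects; an empty list keeps every event.
#' @return The gated `event_table` (possibly with zero rows, returned as a
#'   0-row matrix wrapper; event order preserved).
#' @export
gate_threshold <- function(table, rules) {
  stopifnot(inherits(table, "event_table"))
  if (!table$transformed) {
    stop("gate thresholds are defined on the transformed scale; ",
         "run apply_transform() first", call. = FALSE)
  }
  stopifnot(is.list(rules), all(vapply(rules, inherits, logical(1), "gate_rule")))
  keep <- rep(TRUE, nrow(table$intensities))
  for (r in rules) {
    if (!r$marker %in% colnames(table$intensities)) {
      stop("gate rule references unknown marker '", r$marker, "'", call. = FALSE)
    }
    x <- table$intensities[, r$marker]
    keep <- keep & if (r$direction == "positive") x > r$threshold else x <= r$threshold
  }
  out <- table
  out$intensities <- table$intensities[keep, , drop = FALSE]
  out
}
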