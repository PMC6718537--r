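#' Construct a per-sample event table
#'
#' Holds one sample's events-by-markers intensity matrix together with the
#' sample id, the biological condition (if known) and whether the values are
#' still raw fluorescence or already variance-stabilized.
#'
#' @param intensities Numeric matrix, events x markers; column names are the
#'   marker panel in canonical order.
#' @param sample_id Non-empty string identifying the sample (e.g. one mouse).
#' @param condition Optional condition label; attached later by
#'   [assemble_sample_set()] when missing.
#' @param transformed Logical; `TRUE` once [apply_transform()] has run.
#' @return An object of class `event_table`.
#' @export
event_table <- function(intensities, sample_id, condition = NA_character_,
                        transformed = FALSE) {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop("intensities must be a numeric matrix", call. = FALSE)
  }
  if (nrow(intensities) < 1L) {
    stop("an event table needs at least one event", call. = FALSE)
  }
  if (is.null(colnames(intensities))) {
    stop("intensity columns must be named by marker", call. = FALSE)
  }
  if (any(!is.finite(intensities))) {
    stop("non-finite intensity values in sample ", sample_id, call. = FALSE)
  }
  if (!is.character(sample_id) || length(sample_id) != 1L || !nzchar(sample_id)) {
    stop("sample_id must be a single non-empty string", call. = FALSE)
  }
  structure(
    list(sample_id = sample_id,
         condition = as.character(condition),
         intensities = intensities,
         transformed = isTRUE(transformed)),
    class = "event_table"
  )
}

#' @export
print.event_table <- function(x, ...) {
  cat("event table '", x$sample_id, "': ", nrow(x$intensities), " events x ",
      ncol(x$intensities), " markers (",
      if (x$transformed) "transformed" else "raw", ")\n", sep = "")
  if (!is.na(x$condition)) cat("condition:", x$condition, "\n")
  invisible(x)
}

#' Number of events in an event table
#' @param table An `event_table`.
#' @return Integer event count.
#' @export
n_events <- function(table) {
  stopifnot(inherits(table, "event_table"))
  nrow(table$intensities)
}

#' Assemble per-sample tables and metadata into a sample set
#'
#' Attaches the condition of each sample from a metadata table and checks the
#' two-group design: exactly two condition levels, every sample present once,
#' at least two samples per condition.
#'
#' @param tables List of [event_table()] objects sharing one panel.
#' @param metadata Data frame with columns `sample_id` and `condition`.
#' @param reference Reference condition level. Defaults to the
#'   lexicographically first level; fold changes are reported as
#'   non-reference vs reference.
#' @return An object of class `sample_set` with fields `panel`, `tables`
#'   (named by sample id) and `condition_levels` (reference first).
#' @export
assemble_sample_set <- function(tables, metadata, reference = NULL) {
  if (length(tables) == 0L) stop("no event tables supplied", call. = FALSE)
  stopifnot(all(vapply(tables, inherits, logical(1), "event_table")))
  if (!all(c("sample_id", "condition") %in% names(metadata))) {
    stop("metadata needs columns sample_id and condition", call. = FALSE)
  }
  ids <- vapply(tables, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) {
    stop("duplicate sample_id among event tables: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  meta_id <- as.character(metadata$sample_id)
  if (anyDuplicated(meta_id)) {
    stop("duplicate sample_id in metadata", call. = FALSE)
  }
  missing_meta <- setdiff(ids, meta_id)
  if (length(missing_meta)) {
    stop("samples missing from metadata: ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  }
  orphan <- setdiff(meta_id, ids)
  if (length(orphan)) {
    warning("metadata rows with no event table: ",
            paste(orphan, collapse = ", "), call. = FALSE)
  }
  cond <- as.character(metadata$condition)[match(ids, meta_id)]
  levels_found <- sort(unique(cond))
  if (length(levels_found) != 2L) {
    stop("exactly 2 condition levels required, found ",
         length(levels_found), ": ", paste(levels_found, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(reference)) reference <- levels_found[1L]
  if (!reference %in% levels_found) {
    stop("reference level '", reference, "' not among conditions", call. = FALSE)
  }
  condition_levels <- c(reference, setdiff(levels_found, reference))
  if (any(table(cond) < 2L)) {
    stop("each condition needs at least 2 samples", call. = FALSE)
  }
  panels <- lapply(tables, function(t) colnames(t$intensities))
  if (!all(vapply(panels, identical, logical(1), panels[[1L]]))) {
    stop("all event tables must share one marker panel (same columns, same order)",
         call. = FALSE)
  }
  tables <- Map(function(t, cc) { t$condition <- cc; t }, tables, cond)
  names(tables) <- ids
  structure(
    list(panel = marker_panel(panels[[1L]]),
         tables = tables,
         condition_levels = condition_levels),
    class = "sample_set"
  )
}

#' @export
print.sample_set <- function(x, ...) {
  cond <- sample_conditions(x)
  cat("sample set: ", length(x$tables), " samples, ",
      length(x$panel), " markers\n", sep = "")
  print(table(factor(cond, levels = x$condition_levels)))
  invisible(x)
}

#' Condition factor of a sample set
#'
#' @param samples A `sample_set`.
#' @return Factor of per-sample conditions, reference level first, named by
#'   sample id, in sample order.
#' @export
sample_conditions <- function(samples) {
  stopifnot(inherits(samples, "sample_set"))
  cond <- vapply(samples$tables, `[[`, character(1), "condition")
  factor(cond, levels = samples$condition_levels)
}
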