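#' Define a marker panel
#'
#' A marker panel is the ordered set of surface-marker names measured on every
#' event. The order given here is the canonical column order for every matrix
#' the pipeline produces (event tables, pooled matrices, cluster medians).
#'
#' @param names Character vector of marker names; non-empty and unique.
#' @return A character vector of class `marker_panel`.
#' @examples
#' marker_panel(c("CD90", "CD31"))
#' @export
marker_panel <- function(names) {
  if (!is.character(names) || length(names) == 0L) {
    stop("a marker panel needs at least one marker name", call. = FALSE)
  }
  if (anyNA(names) || any(!nzchar(names))) {
    stop("marker names must be non-missing and non-empty", call. = FALSE)
  }
  if (anyDuplicated(names)) {
    stop("duplicated marker name(s): ",
         paste(unique(names[duplicated(names)]), collapse = ", "),
         call. = FALSE)
  }
  structure(as.character(names), class = "marker_panel")
}

#' The default 7-marker cardiac stroma panel
#'
#' Sca-1, PDGFRa (CD140a), CD31, CD45, CD34, CD90 and CD73: the conventional
#' panel for resolving cardiac mesenchymal stromal cells (Sca-1+ PDGFRa+
#' CD31- CD45-) from endothelial (CD31+) and immune (CD45+) stroma.
#'
#' @return A [marker_panel()] of length 7.
#' @export
default_panel <- function() {
  marker_panel(c("Sca1", "PDGFRa", "CD31", "CD45", "CD34", "CD90", "CD73"))
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("marker panel (", length(x), " markers): ",
      paste(unclass(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}
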