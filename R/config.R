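# Run configuration: one YAML file fully determines a run (together with the
# seed). Unknown keys are rejected rather than ignored so typos cannot
# silently fall back to defaults.

config_defaults <- function() {
  list(
    inputs = NULL,                  # character vector of event files, or a dir
    metadata = NULL,                # metadata CSV path
    panel = unclass(default_panel()),
    reference = NULL,               # reference condition; default lexicographic
    transform = list(kind = "arcsinh", cofactor = 150),
    gating = list(),                # list of {marker, direction, threshold}
    clustering = list(linkage = "ward", metric = "euclidean",
                      per_sample_cap = 1000L, k = 15L, height = NULL),
    test = list(sig_threshold = 0.05, shrink_dispersion = FALSE),
    simulate = list(truth = "default", format = "fcs"),
    figure_format = "png",
    output_dir = "decyt_out",
    seed = 1L
  )
}

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop("unknown config key(s) in ", where, ": ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
}

#' Read and validate a run configuration
#'
#' Merges the YAML file over the package defaults; unknown keys anywhere in
#' the file are an error.
#'
#' @param path YAML config file, or `NULL` for pure defaults.
#' @param overrides Named list applied on top (e.g. from command-line
#'   flags).
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  defaults <- config_defaults()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  check_keys(user, names(defaults), "top level")
  for (section in c("transform", "clustering", "test", "simulate")) {
    if (!is.null(user[[section]])) {
      check_keys(user[[section]], names(defaults[[section]]), section)
    }
  }
  cfg <- utils::modifyList(defaults, user, keep.null = TRUE)
  cfg <- utils::modifyList(cfg, overrides, keep.null = TRUE)
  if (!cfg$transform$kind %in% c("arcsinh", "identity")) {
    stop("transform.kind must be arcsinh or identity", call. = FALSE)
  }
  if (!cfg$clustering$linkage %in% c("ward", "average", "complete")) {
    stop("clustering.linkage must be ward, average or complete", call. = FALSE)
  }
  if (!is.null(cfg$clustering$k) && !is.null(cfg$clustering$height)) {
    # height wins when both are set explicitly by the user
    if (!is.null(user$clustering$height)) cfg$clustering$k <- NULL
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

write_config_snapshot <- function(cfg, dir) {
  snap <- file.path(dir, "config_snapshot.yaml")
  yaml::write_yaml(unclass(cfg), snap)
  snap
}
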