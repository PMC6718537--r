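# Synthetic multi-sample cytometry experiments with known subpopulation
# structure and planted differential abundance. Per-sample proportion noise
# is Dirichlet-multinomial: proportions are drawn from a Dirichlet centred on
# the condition's population mix with concentration kappa, then event
# populations multinomially — this produces the extra-multinomial
# (mouse-to-mouse) variance the NB abundance test must face.

#' Describe a synthetic cytometry experiment
#'
#' @param means Populations x markers matrix of population mean intensities
#'   on the transformed (arcsinh) scale; column names are the panel.
#' @param sds Positive per-population, per-marker SDs: a matrix like `means`,
#'   a per-population vector, or one scalar. Populations are Gaussian with
#'   diagonal covariance on the transformed scale.
#' @param base_proportions Reference-condition population frequencies; must
#'   sum to 1.
#' @param fold_changes Per-population multiplicative abundance shift in the
#'   non-reference condition (1 = no change); shifted proportions are
#'   renormalized to a simplex.
#' @param concentration Dirichlet concentration of per-sample proportion
#'   noise; larger = less mouse-to-mouse variability. Default 200.
#' @param cells_per_sample Events acquired per sample. Default 10000.
#' @param n_reference,n_other Samples per condition. Default 5 vs 4.
#' @param condition_levels Labels, reference first. Default young/aged.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(means, sds = 0.35,
                            base_proportions = NULL,
                            fold_changes = NULL,
                            concentration = 200,
                            cells_per_sample = 10000L,
                            n_reference = 5L, n_other = 4L,
                            condition_levels = c("young", "aged")) {
  means <- as.matrix(means)
  n_pop <- nrow(means)
  if (is.null(colnames(means))) {
    stop("means must have marker column names", call. = FALSE)
  }
  if (length(sds) == 1L) sds <- matrix(sds, n_pop, ncol(means))
  else if (is.null(dim(sds))) sds <- matrix(sds, n_pop, ncol(means))
  sds <- as.matrix(sds)
  stopifnot(all(dim(sds) == dim(means)))
  if (any(sds <= 0)) stop("population SDs must be > 0", call. = FALSE)
  if (is.null(base_proportions)) base_proportions <- rep(1 / n_pop, n_pop)
  if (length(base_proportions) != n_pop || any(base_proportions <= 0) ||
      abs(sum(base_proportions) - 1) > 1e-8) {
    stop("base_proportions must be a positive simplex over the populations",
         call. = FALSE)
  }
  if (is.null(fold_changes)) fold_changes <- rep(1, n_pop)
  if (length(fold_changes) != n_pop || any(fold_changes <= 0)) {
    stop("fold_changes must be positive, one per population", call. = FALSE)
  }
  if (!is.numeric(concentration) || concentration <= 0) {
    stop("concentration must be > 0", call. = FALSE)
  }
  stopifnot(cells_per_sample >= 1L, n_reference >= 2L, n_other >= 2L,
            length(condition_levels) == 2L)
  structure(
    list(means = means, sds = sds,
         base_proportions = base_proportions / sum(base_proportions),
         fold_changes = fold_changes,
         concentration = concentration,
         cells_per_sample = as.integer(cells_per_sample),
         n_reference = as.integer(n_reference),
         n_other = as.integer(n_other),
         condition_levels = as.character(condition_levels)),
    class = "synthetic_truth"
  )
}

#' Condition-specific population proportions of a truth
#'
#' Reference proportions are `base_proportions`; non-reference proportions
#' are `base_proportions * fold_changes` renormalized.
#'
#' @param truth A [synthetic_truth()].
#' @return List with elements `reference` and `other`, each a simplex.
#' @export
truth_proportions <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  shifted <- truth$base_proportions * truth$fold_changes
  list(reference = truth$base_proportions, other = shifted / sum(shifted))
}

#' The default experiment mimicking an aging cardiac stroma design
#'
#' Fifteen Gaussian populations over the 7-marker panel of
#' [default_panel()], 5 reference ("young") vs 4 non-reference ("aged")
#' samples, 10,000 cells each. Population phenotypes are binary-coded
#' high/low archetypes of cardiac stroma: immune (CD45+), endothelial
#' (CD31+) and mesenchymal stromal (Sca-1+ PDGFRa+ CD31- CD45-)
#' compartments, the latter split by CD90/CD73/CD34. One major CD90-high
#' stromal population is halved in the aged-like condition while two
#' CD90-low stromal populations and a rare CD31+ CD90+ population double, so
#' a correct analysis flags the CD90-high subset as
#' reference(young)-enriched. The planted shifts are mass-balanced (the
#' fold-weighted proportions still sum to 1), so renormalization leaves the
#' unshifted populations at their reference frequencies and "differential"
#' ground truth stays well-defined.
#'
#' @return A [synthetic_truth()] with 15 populations and 9 samples.
#' @export
default_paper_like_truth <- function() {
  panel <- unclass(default_panel())
  hi <- 4; lo <- 0.5
  # rows: populations p1..p15; columns: Sca1, PDGFRa, CD31, CD45, CD34, CD90, CD73
  code <- rbind(
    p1  = c(1, 1, 0, 0, 1, 0, 0),  # stromal CD90- CD73-
    p2  = c(1, 1, 0, 0, 1, 1, 1),  # stromal CD90+ CD73+
    p3  = c(0, 0, 0, 1, 0, 0, 0),  # immune CD45+
    p4  = c(1, 1, 0, 0, 1, 0, 1),  # stromal CD90- CD73+
    p5  = c(1, 0, 1, 0, 1, 0, 1),  # endothelial CD31+
    p6  = c(0, 0, 1, 0, 0, 0, 0),  # endothelial CD34-
    p7  = c(0, 0, 0, 1, 1, 0, 0),  # immune CD34+
    p8  = c(1, 1, 0, 0, 1, 1, 0),  # stromal CD90+ CD73-  (depleted with age)
    p9  = c(1, 0, 0, 1, 0, 0, 1),  # immune Sca1+
    p10 = c(0, 1, 0, 0, 1, 0, 0),  # stromal Sca1-
    p11 = c(1, 0, 1, 0, 0, 0, 0),  # endothelial CD34- Sca1+
    p12 = c(0, 1, 0, 0, 0, 0, 1),  # stromal CD34-
    p13 = c(1, 0, 1, 0, 1, 1, 0),  # endothelial CD90+
    p14 = c(1, 1, 1, 0, 1, 1, 0),  # CD31+ stromal (emerges with age)
    p15 = c(0, 0, 0, 0, 0, 0, 0)   # all-low debris-like
  )
  means <- code * hi + (1 - code) * lo
  colnames(means) <- panel
  base <- c(0.04, 0.11, 0.12, 0.09, 0.08, 0.07, 0.06, 0.15,
            0.05, 0.05, 0.04, 0.02, 0.03, 0.015, 0.075)
  fold <- rep(1, 15)
  fold[8] <- 0.5               # CD90-high stromal subset halved with aging
  fold[c(1, 12, 14)] <- 2      # CD90-low stromal and CD31+ subsets doubled
  # mass balance: sum(base * fold) == 1, so unshifted populations keep their
  # reference-condition frequencies after renormalization
  stopifnot(abs(sum(base) - 1) < 1e-12, abs(sum(base * fold) - 1) < 1e-12)
  synthetic_truth(means = means, sds = 0.35, base_proportions = base,
                  fold_changes = fold)
}

#' Simulate a full cytometry experiment from a truth
#'
#' For each sample: draws its population mix from
#' Dirichlet(concentration x condition proportions), assigns each event a
#' population multinomially, and draws marker values from the population's
#' Gaussian on the transformed scale. With `emit_raw = TRUE` values are
#' back-converted to the raw fluorescence scale (`sinh(x) * cofactor`) and
#' tables are flagged untransformed, for writing realistic FCS/CSV fixtures.
#'
#' @param truth A [synthetic_truth()].
#' @param seed Integer seed; the same truth and seed give byte-identical
#'   event matrices.
#' @param emit_raw Emit raw-scale intensities instead of transformed ones.
#' @param cofactor Arcsinh cofactor used when `emit_raw = TRUE`.
#' @return List with `samples` (a `sample_set`), `labels` (list of
#'   per-event true population ids, by sample) and `metadata` (data frame).
#' @export
simulate_experiment <- function(truth, seed = 1L, emit_raw = FALSE,
                                cofactor = 150) {
  stopifnot(inherits(truth, "synthetic_truth"))
  props <- truth_proportions(truth)
  n_pop <- nrow(truth$means)
  ids <- c(sprintf("y%d", seq_len(truth$n_reference)),
           sprintf("o%d", seq_len(truth$n_other)))
  conds <- rep(truth$condition_levels, c(truth$n_reference, truth$n_other))
  sim <- with_seed(seed, {
    lapply(seq_along(ids), function(j) {
      target <- if (conds[j] == truth$condition_levels[1L])
        props$reference else props$other
      p <- rdirichlet1(truth$concentration * target)
      pop <- sample.int(n_pop, truth$cells_per_sample, replace = TRUE, prob = p)
      x <- truth$means[pop, , drop = FALSE] +
        matrix(stats::rnorm(length(pop) * ncol(truth$means)),
               nrow = length(pop)) * truth$sds[pop, , drop = FALSE]
      colnames(x) <- colnames(truth$means)
      list(x = x, pop = pop)
    })
  })
  tables <- lapply(seq_along(ids), function(j) {
    x <- sim[[j]]$x
    if (emit_raw) {
      x <- sinh(x) * cofactor
      event_table(x, sample_id = ids[j], transformed = FALSE)
    } else {
      event_table(x, sample_id = ids[j], transformed = TRUE)
    }
  })
  metadata <- data.frame(sample_id = ids, condition = conds)
  samples <- assemble_sample_set(tables, metadata,
                                 reference = truth$condition_levels[1L])
  labels <- stats::setNames(lapply(sim, `[[`, "pop"), ids)
  list(samples = samples, labels = labels, metadata = metadata)
}

#' Simulate a clusters-by-samples count matrix directly
#'
#' The count-level view of [simulate_experiment()]: per-sample
#' Dirichlet-multinomial cluster counts without drawing marker values.
#' Useful for statistical calibration studies of the abundance stage, where
#' thousands of replicates are needed.
#'
#' @inheritParams simulate_experiment
#' @return List with `counts` (matrix), `condition` (factor, reference
#'   first) and `differential` (logical per cluster, `fold_changes != 1`).
#' @export
simulate_cluster_counts <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  props <- truth_proportions(truth)
  n_pop <- nrow(truth$means)
  ids <- c(sprintf("y%d", seq_len(truth$n_reference)),
           sprintf("o%d", seq_len(truth$n_other)))
  conds <- rep(truth$condition_levels, c(truth$n_reference, truth$n_other))
  counts <- with_seed(seed, {
    vapply(seq_along(ids), function(j) {
      target <- if (conds[j] == truth$condition_levels[1L])
        props$reference else props$other
      p <- rdirichlet1(truth$concentration * target)
      as.numeric(stats::rmultinom(1L, truth$cells_per_sample, p))
    }, numeric(n_pop))
  })
  dimnames(counts) <- list(paste0("c", seq_len(n_pop)), ids)
  list(counts = counts,
       condition = factor(conds, levels = truth$condition_levels),
       differential = truth$fold_changes != 1)
}

#' Load a truth specification from JSON
#'
#' Reads the schema written by [write_fixture()].
#'
#' @param path Path to a `truth.json`.
#' @return A [synthetic_truth()].
#' @export
truth_from_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  means <- as.matrix(j$means)
  colnames(means) <- j$panel
  synthetic_truth(
    means = means, sds = as.matrix(j$sds),
    base_proportions = j$base_proportions,
    fold_changes = j$fold_changes,
    concentration = j$concentration,
    cells_per_sample = j$cells_per_sample,
    n_reference = j$n_reference, n_other = j$n_other,
    condition_levels = j$condition_levels)
}

#' Write a simulated experiment to disk as a fixture
#'
#' One FCS or CSV file per sample, a `metadata.csv`, and a `truth.json`
#' describing the generating parameters (and true labels when given).
#'
#' @param samples A `sample_set` (e.g. from [simulate_experiment()] with
#'   `emit_raw = TRUE` for FCS).
#' @param dir Output directory, created if needed.
#' @param format `"fcs"` or `"csv"`.
#' @param truth Optional [synthetic_truth()] to serialize alongside.
#' @return Character vector of the per-sample file paths, invisibly.
#' @export
write_fixture <- function(samples, dir, format = c("fcs", "csv"), truth = NULL) {
  stopifnot(inherits(samples, "sample_set"))
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(samples$tables, function(t) {
    path <- file.path(dir, paste0(t$sample_id, ".", format))
    if (format == "fcs") {
      write_fcs(t, path)
    } else {
      utils::write.csv(as.data.frame(t$intensities), path, row.names = FALSE)
    }
    path
  }, character(1))
  meta <- data.frame(
    sample_id = names(samples$tables),
    condition = vapply(samples$tables, `[[`, character(1), "condition"))
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  if (!is.null(truth)) {
    stopifnot(inherits(truth, "synthetic_truth"))
    jsonlite::write_json(
      list(panel = colnames(truth$means),
           means = truth$means, sds = truth$sds,
           base_proportions = truth$base_proportions,
           fold_changes = truth$fold_changes,
           concentration = truth$concentration,
           cells_per_sample = truth$cells_per_sample,
           n_reference = truth$n_reference, n_other = truth$n_other,
           condition_levels = truth$condition_levels),
      file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  }
  invisible(paths)
}
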