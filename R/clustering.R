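#' Pool transformed events across samples
#'
#' Concatenates all samples' events (in sample order) into one matrix for
#' tree building, keeping per-row provenance. A per-sample cap draws a
#' reproducible subsample without replacement — agglomerative clustering
#' stores an O(n^2) distance matrix, so trees are built on a capped pool and
#' the remaining events are assigned to the tree afterwards by
#' [assign_full()].
#'
#' @param samples A transformed `sample_set`.
#' @param per_sample_cap Maximum events per sample entering the tree, or
#'   `NULL` for all events. Default 1000 (9 samples give a 9000-row tree).
#' @param seed Integer seed making the subsample reproducible.
#' @return An object of class `pooled_events` with fields `intensities`,
#'   `sample_id` (per row), `row_index` (event index within its sample),
#'   `per_sample_cap` and `seed`.
#' @export
pool_events <- function(samples, per_sample_cap = 1000L, seed = 1L) {
  stopifnot(inherits(samples, "sample_set"))
  if (length(samples$tables) == 0L) stop("empty sample set", call. = FALSE)
  if (!all(vapply(samples$tables, `[[`, logical(1), "transformed"))) {
    stop("all tables must be transformed before pooling", call. = FALSE)
  }
  picks <- with_seed(seed, lapply(samples$tables, function(t) {
    n <- nrow(t$intensities)
    if (is.null(per_sample_cap) || n <= per_sample_cap) {
      if (!is.null(per_sample_cap) && n < per_sample_cap) {
        warning("sample '", t$sample_id, "' has ", n,
                " events, fewer than the cap of ", per_sample_cap, call. = FALSE)
      }
      seq_len(n)
    } else {
      sort(sample.int(n, per_sample_cap))
    }
  }))
  intensities <- do.call(rbind, Map(function(t, idx)
    t$intensities[idx, , drop = FALSE], samples$tables, picks))
  rownames(intensities) <- NULL
  structure(
    list(intensities = intensities,
         sample_id = rep(names(samples$tables), lengths(picks)),
         row_index = unlist(picks, use.names = FALSE),
         per_sample_cap = per_sample_cap,
         seed = seed),
    class = "pooled_events"
  )
}

#' Build the hierarchical tree over pooled events
#'
#' Agglomerative clustering of pooled events in transformed marker space.
#' Ward linkage (on Euclidean distances) is the default: it favours compact,
#' roughly spherical clusters, matching the discrete phenotype blocks that
#' marker-median heatmaps display.
#'
#' @param pooled A [pool_events()] result.
#' @param linkage `"ward"`, `"average"` or `"complete"`.
#' @param metric Distance metric; only `"euclidean"` is supported.
#' @return An (uncut) object of class `cluster_model` wrapping the
#'   [stats::hclust] tree and the pooled events.
#' @export
build_tree <- function(pooled, linkage = c("ward", "average", "complete"),
                       metric = "euclidean") {
  stopifnot(inherits(pooled, "pooled_events"))
  linkage <- match.arg(linkage)
  metric <- match.arg(metric, "euclidean")
  x <- pooled$intensities
  if (nrow(x) < 2L) stop("need at least 2 pooled events to build a tree", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite intensities in pooled events", call. = FALSE)
  method <- c(ward = "ward.D2", average = "average", complete = "complete")[[linkage]]
  tree <- stats::hclust(stats::dist(x, method = metric), method = method)
  structure(
    list(tree = tree, pooled = pooled, linkage = linkage, metric = metric,
         cut = NULL, labels = NULL, centroids = NULL, n_clusters = NULL),
    class = "cluster_model"
  )
}

# Deterministic cluster ids: 1..n by decreasing size, ties broken by the
# lowest member row index in the pooled matrix.
relabel_by_size <- function(raw_labels) {
  sizes <- table(raw_labels)
  first_row <- tapply(seq_along(raw_labels), raw_labels, min)
  ord <- order(-as.integer(sizes), as.integer(first_row))
  remap <- integer(length(sizes))
  remap[as.integer(names(sizes))[ord]] <- seq_along(ord)
  remap[raw_labels]
}

#' Cut the tree into subpopulations
#'
#' Partitions the pooled events either at a fixed merge height (clusters are
#' the connected components once merges above that height are removed) or
#' into a requested number of clusters `k`. Cluster ids are assigned 1..n in
#' decreasing cluster-size order (ties by lowest pooled row index), and
#' per-cluster marker medians (centroids) are computed from the pooled
#' members.
#'
#' @param model A `cluster_model` from [build_tree()].
#' @param k Number of clusters (default 15), or `NULL` when cutting by height.
#' @param height Merge height at which to cut, or `NULL` when cutting by `k`.
#' @return The `cluster_model` with `labels`, `centroids` and `n_clusters`
#'   filled in.
#' @export
cut_tree <- function(model, k = 15L, height = NULL) {
  stopifnot(inherits(model, "cluster_model"))
  if (is.null(model$tree)) stop("model has no tree", call. = FALSE)
  n_leaves <- length(model$tree$order)
  if (!is.null(height)) {
    if (!is.finite(height) || height < 0) stop("cut height must be >= 0", call. = FALSE)
    raw <- stats::cutree(model$tree, h = height)
    model$cut <- list(height = height)
  } else {
    if (is.null(k) || k < 1L || k > n_leaves) {
      stop("k must lie in 1..", n_leaves, call. = FALSE)
    }
    raw <- stats::cutree(model$tree, k = k)
    model$cut <- list(k = as.integer(k))
  }
  labels <- relabel_by_size(raw)
  model$labels <- labels
  model$n_clusters <- max(labels)
  med <- t(vapply(seq_len(model$n_clusters), function(c)
    apply(model$pooled$intensities[labels == c, , drop = FALSE], 2L, stats::median),
    numeric(ncol(model$pooled$intensities))))
  rownames(med) <- paste0("c", seq_len(model$n_clusters))
  model$centroids <- med
  model
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("cluster model: ", length(x$tree$order), " pooled events, ",
      x$linkage, " linkage\n", sep = "")
  if (!is.null(x$labels)) {
    cat("cut into ", x$n_clusters, " clusters (",
        paste(names(x$cut), unlist(x$cut), sep = " = "), ")\n", sep = "")
  } else cat("tree not yet cut\n")
  invisible(x)
}

#' Label every event of every sample
#'
#' Events that entered the tree keep their tree label; events left out by the
#' per-sample cap receive the label of the nearest cluster centroid
#' (Euclidean distance on the transformed scale, ties to the lowest cluster
#' id). With no cap this is the identity on tree labels.
#'
#' @param model A cut `cluster_model`.
#' @param samples The transformed `sample_set` the tree was pooled from.
#' @return A data frame of class `cluster_labels` with columns `sample_id`,
#'   `event` (row index within the sample) and `cluster`; one row per event
#'   of every sample.
#' @export
assign_full <- function(model, samples) {
  stopifnot(inherits(model, "cluster_model"), inherits(samples, "sample_set"))
  if (is.null(model$labels)) stop("cut the tree before assigning events", call. = FALSE)
  cent <- model$centroids
  out <- lapply(names(samples$tables), function(sid) {
    tab <- samples$tables[[sid]]
    n <- nrow(tab$intensities)
    lab <- integer(n)
    in_pool <- model$pooled$sample_id == sid
    lab[model$pooled$row_index[in_pool]] <- model$labels[in_pool]
    todo <- which(lab == 0L)
    if (length(todo)) {
      x <- tab$intensities[todo, , drop = FALSE]
      # squared distances to each centroid; ties resolve to lowest id since
      # max.col on -d2 with ties.method "first" scans ids in order
      d2 <- outer(rowSums(x^2), rowSums(cent^2), "+") - 2 * x %*% t(cent)
      lab[todo] <- max.col(-d2, ties.method = "first")
    }
    data.frame(sample_id = sid, event = seq_len(n), cluster = lab)
  })
  res <- do.call(rbind, out)
  class(res) <- c("cluster_labels", class(res))
  res
}

#' Per-cluster marker medians over all labeled events
#'
#' Entry (c, m) is the median transformed intensity of marker m over every
#' event assigned to cluster c (even-sized sets use the mean of the central
#' pair). Unlike the tree centroids, these medians cover all events, not just
#' the pooled subsample.
#'
#' @param labels A [assign_full()] result covering every event.
#' @param samples The transformed `sample_set`.
#' @return Matrix clusters x markers, rows named `c1..cn`.
#' @export
cluster_medians <- function(labels, samples) {
  stopifnot(inherits(labels, "cluster_labels"), inherits(samples, "sample_set"))
  all_int <- do.call(rbind, lapply(samples$tables, `[[`, "intensities"))
  lab_order <- unlist(lapply(names(samples$tables), function(sid) {
    sub <- labels[labels$sample_id == sid, ]
    sub$cluster[order(sub$event)]
  }))
  stopifnot(length(lab_order) == nrow(all_int), all(lab_order >= 1L))
  n_clusters <- max(lab_order)
  med <- t(vapply(seq_len(n_clusters), function(c) {
    members <- all_int[lab_order == c, , drop = FALSE]
    stopifnot(nrow(members) > 0L)
    apply(members, 2L, stats::median)
  }, numeric(ncol(all_int))))
  dimnames(med) <- list(paste0("c", seq_len(n_clusters)), colnames(all_int))
  med
}

#' Export the dendrogram as Newick
#'
#' Merge heights become branch lengths; leaves are pooled row indices.
#'
#' @param model A `cluster_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(model, path) {
  stopifnot(inherits(model, "cluster_model"))
  ape_tree <- ape::as.phylo(model$tree)
  ape::write.tree(ape_tree, file = path)
  invisible(path)
}
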