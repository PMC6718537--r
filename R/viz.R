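# The tri-panel report: cluster phenotype (marker medians), per-sample
# relative counts, and the enrichment significance strip, under one shared
# cluster row order.

#' Within-sample relative cluster counts
#'
#' Entry (c, j) is the proportion of sample j's cells in cluster c; each
#' column sums to 1.
#'
#' @param counts Clusters x samples count matrix with positive column sums.
#' @return Proportion matrix of the same shape.
#' @export
relative_counts <- function(counts) {
  counts <- as.matrix(counts)
  tot <- colSums(counts)
  if (any(tot <= 0)) {
    stop("sample(s) with zero total count: ",
         paste(colnames(counts)[tot <= 0], collapse = ", "), call. = FALSE)
  }
  sweep(counts, 2L, tot, "/")
}

#' Assemble the three aligned heatmap panels
#'
#' Combines cluster marker medians, per-sample relative counts and the
#' per-cluster enrichment direction into one bundle sharing a cluster row
#' order. Marker medians are additionally min-max scaled per marker to
#' \[0, 1\] for display; the raw medians are always retained.
#'
#' @param medians Clusters x markers median matrix ([cluster_medians()]).
#' @param counts Clusters x samples count matrix ([tabulate_counts()]).
#' @param result [nb_wald_test()] result data frame.
#' @param condition Factor of per-sample conditions (column grouping).
#' @param order Row ordering: `"tree"` (dendrogram over cluster medians,
#'   groups phenotypically similar clusters; default), `"size"` (total cells
#'   descending) or `"significance"` (adjusted p ascending).
#' @return An object of class `heatmap_bundle`.
#' @export
build_heatmap_bundle <- function(medians, counts, result, condition,
                                 order = c("tree", "size", "significance")) {
  order <- match.arg(order)
  medians <- as.matrix(medians); counts <- as.matrix(counts)
  n <- nrow(medians)
  if (nrow(counts) != n || nrow(result) != n) {
    stop("medians, counts and result must cover the same clusters", call. = FALSE)
  }
  row_order <- switch(order,
    size = order(rowSums(counts), decreasing = TRUE),
    significance = order(ifelse(is.na(result$padj), Inf, result$padj)),
    tree = if (n > 2L)
      stats::hclust(stats::dist(medians), method = "ward.D2")$order
    else seq_len(n)
  )
  rng <- apply(medians, 2L, range)
  span <- pmax(rng[2L, ] - rng[1L, ], .Machine$double.eps)
  scaled <- sweep(sweep(medians, 2L, rng[1L, ], "-"), 2L, span, "/")
  structure(
    list(median_panel = medians,
         median_panel_scaled = scaled,
         relcount_panel = relative_counts(counts),
         signif_strip = stats::setNames(result$direction, result$cluster),
         condition = condition,
         row_order = row_order),
    class = "heatmap_bundle"
  )
}

#' Render the tri-panel heatmap
#'
#' Left: per-marker scaled cluster medians; middle: within-sample relative
#' counts with samples grouped by condition; right: significance strip
#' (default colors: reference/young-enriched green, other/aged-enriched
#' orange).
#'
#' @param bundle A [build_heatmap_bundle()] result.
#' @param path Output file path.
#' @param format `"png"`, `"svg"` or `"pdf"`; default from the file
#'   extension.
#' @param width,height Figure size in inches.
#' @param colors Named list overriding `reference`/`other`/`none` strip
#'   colors.
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(bundle, path, format = NULL,
                           width = 9, height = 5, colors = list()) {
  stopifnot(inherits(bundle, "heatmap_bundle"))
  if (is.null(format)) format <- tolower(sub(".*\\.", "", path))
  if (!format %in% c("png", "svg", "pdf")) {
    stop("unknown figure format '", format, "'", call. = FALSE)
  }
  cols <- utils::modifyList(
    list(reference = "#2e8b57", other = "#e69500", none = "grey85"), colors)

  ord <- bundle$row_order
  clusters <- rownames(bundle$median_panel)
  if (is.null(clusters)) clusters <- paste0("c", seq_len(nrow(bundle$median_panel)))
  lev <- clusters[rev(ord)]   # first row of the order on top

  melt <- function(m, what) {
    data.frame(cluster = factor(rep(rownames(m), ncol(m)), levels = lev),
               column = factor(rep(colnames(m), each = nrow(m)),
                               levels = colnames(m)),
               value = as.vector(m), panel = what)
  }
  med <- bundle$median_panel_scaled
  rownames(med) <- clusters
  rel <- bundle$relcount_panel
  rownames(rel) <- clusters
  if (!is.null(bundle$condition)) {
    rel <- rel[, order(bundle$condition), drop = FALSE]
  }
  strip <- data.frame(
    cluster = factor(clusters, levels = lev),
    column = "enrichment",
    direction = factor(unname(bundle$signif_strip),
                       levels = c("enriched_in_reference", "none",
                                  "enriched_in_other")))

  p1 <- ggplot2::ggplot(melt(med, "median"),
                        ggplot2::aes(x = column, y = cluster,
                                     fill = value)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_viridis_c(name = "scaled\nmedian", limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, title = "Marker medians") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  p2 <- ggplot2::ggplot(melt(rel, "relcount"),
                        ggplot2::aes(x = column, y = cluster,
                                     fill = value)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_gradient(name = "fraction\nof sample",
                                 low = "white", high = "#27408b") +
    ggplot2::labs(x = NULL, y = NULL, title = "Relative counts") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  p3 <- ggplot2::ggplot(strip,
                        ggplot2::aes(x = column, y = cluster,
                                     fill = direction)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_manual(
      name = "enriched in",
      values = c(enriched_in_reference = cols$reference,
                 none = cols$none,
                 enriched_in_other = cols$other),
      drop = FALSE) +
    ggplot2::labs(x = NULL, y = NULL, title = "Significance") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text = ggplot2::element_blank())
  fig <- patchwork::wrap_plots(p1, p2, p3, widths = c(3, 3.5, 0.7))

  dev <- switch(format,
    png = function(f) grDevices::png(f, width = width, height = height,
                                     units = "in", res = 150),
    svg = function(f) grDevices::svg(f, width = width, height = height),
    pdf = function(f) grDevices::pdf(f, width = width, height = height))
  dev(path)
  print(fig)
  grDevices::dev.off()
  invisible(path)
}

#' Export the bundle's panels as CSV
#'
#' Writes the unscaled medians, relative counts and significance strip so
#' the figure is fully regenerable from text files.
#'
#' @param bundle A `heatmap_bundle`.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_bundle_csv <- function(bundle, dir) {
  stopifnot(inherits(bundle, "heatmap_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    medians = file.path(dir, "cluster_medians.csv"),
    relcounts = file.path(dir, "relative_counts.csv"),
    strip = file.path(dir, "significance_strip.csv"))
  utils::write.csv(bundle$median_panel, paths["medians"])
  utils::write.csv(bundle$relcount_panel, paths["relcounts"])
  utils::write.csv(
    data.frame(cluster = names(bundle$signif_strip),
               direction = unname(bundle$signif_strip),
               row_order = order(bundle$row_order)),
    paths["strip"], row.names = FALSE)
  invisible(paths)
}
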