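#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a pipeline fit into one row per node
#'
#' Cells and projected genes with their final 2D coordinates, cluster and
#' assignment source.
#'
#' @param x A `stardust_fit`.
#' @param ... Unused.
#' @return Tibble: `node_id`, `node_type`, `x`, `y`, `cluster`, `source`.
#' @export
tidy.stardust_fit <- function(x, ...) {
  cells <- x$cell_coords
  cells$cluster <- x$labels$cluster[match(cells$node_id, x$labels$cell_id)]
  cells$source <- x$labels$source[match(cells$node_id, x$labels$cell_id)]
  genes <- x$gene_coords
  if (nrow(genes)) genes$source <- "projection"
  dplyr::bind_rows(cells, genes)
}

#' One-row summary of a pipeline fit
#'
#' @param x A `stardust_fit`.
#' @param ... Unused.
#' @return Tibble: `n_cells`, `n_genes_projected`, `n_clusters`,
#'   `n_noise`, `silhouette`, `seed`.
#' @export
glance.stardust_fit <- function(x, ...) {
  lab <- x$labels$cluster[match(x$cell_coords$node_id, x$labels$cell_id)]
  sil <- tryCatch(silhouette_score(x$cell_coords, lab), error = function(e) NA_real_)
  tibble(
    n_cells = nrow(x$cell_coords),
    n_genes_projected = nrow(x$gene_coords),
    n_clusters = length(setdiff(unique(lab), -1L)),
    n_noise = sum(lab == -1L),
    silhouette = sil,
    seed = x$config$seed
  )
}

#' Co-embedding plot of cells and marker genes
#'
#' Cells colored by cluster (noise in grey), with projected marker genes
#' inscribed as text labels at their co-embedded positions.
#'
#' @param object A `stardust_fit`.
#' @param genes_per_cluster How many top markers to label per cluster
#'   (default 1; the paper-style display labels the top gene).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stardust_fit <- function(object, genes_per_cluster = 1, ...) {
  df <- tidy(object)
  cells <- df[df$node_type == "cell", ]
  cells$cluster_f <- factor(ifelse(cells$cluster == -1, "noise", cells$cluster))
  genes <- df[df$node_type == "gene", ]
  if (nrow(genes)) {
    genes <- dplyr::slice_head(
      dplyr::group_by(dplyr::left_join(
        genes, object$top_markers[, c("gene_id", "cluster", "rank_in_cluster")],
        by = c(node_id = "gene_id", cluster = "cluster")), .data$cluster),
      n = genes_per_cluster)
    genes <- dplyr::ungroup(genes)
  }
  p <- ggplot2::ggplot(cells, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$cluster_f), size = 0.7,
                        alpha = 0.8) +
    ggplot2::scale_color_discrete(name = "cluster") +
    ggplot2::labs(x = "dim 1", y = "dim 2") +
    ggplot2::theme_minimal()
  if (nrow(genes)) {
    if (requireNamespace("ggrepel", quietly = TRUE)) {
      p <- p + ggrepel::geom_text_repel(data = genes,
                                        ggplot2::aes(label = .data$node_id),
                                        fontface = "italic", size = 3)
    } else {
      p <- p + ggplot2::geom_text(data = genes,
                                  ggplot2::aes(label = .data$node_id),
                                  fontface = "italic", size = 3)
    }
  }
  p
}

#' Plot cluster zonation scores on bin coordinates
#'
#' @param scores Output of [zonation_scores()].
#' @param binmap The `stardust_binmap` providing bin coordinates.
#' @param binarized Plot the thresholded mask instead of the continuous
#'   score (requires `selected` column).
#' @return A ggplot object, faceted by cluster.
#' @export
plot_zonation <- function(scores, binmap, binarized = FALSE) {
  co <- as.data.frame(binmap$coords[scores$bin_id, 1:2, drop = FALSE])
  names(co) <- c("x", "y")
  df <- cbind(as.data.frame(scores), co)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL)
  if (binarized) {
    p + ggplot2::geom_point(ggplot2::aes(color = .data$selected), size = 1) +
      ggplot2::scale_color_manual(values = c(`FALSE` = "grey85",
                                             `TRUE` = "firebrick"))
  } else {
    p + ggplot2::geom_point(ggplot2::aes(color = .data$score), size = 1) +
      ggplot2::scale_color_viridis_c()
  }
}

#' Write the outputs of a pipeline fit
#'
#' Writes `coordinates.csv` (id, type, x, y, cluster), `markers.csv`,
#' `pass_log.csv` and a `run-manifest.txt` with every resolved parameter,
#' into `dir`.
#'
#' @param fit A `stardust_fit`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_stardust <- function(fit, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.table(as.data.frame(tidy(fit)[, c("node_id", "node_type", "x", "y",
                                          "cluster")]),
              file.path(dir, "coordinates.csv"), sep = ",", quote = FALSE,
              row.names = FALSE)
  write.table(as.data.frame(fit$markers), file.path(dir, "markers.csv"),
              sep = ",", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(fit$pass_log), file.path(dir, "pass_log.csv"),
              sep = ",", quote = FALSE, row.names = FALSE)
  cfg <- fit$config
  manifest <- vapply(names(cfg), function(nm) {
    paste0(nm, " = ", paste(format(cfg[[nm]]), collapse = " "))
  }, character(1))
  writeLines(manifest, file.path(dir, "run-manifest.txt"))
  invisible(dir)
}
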