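# Deterministic synthetic-data generators. These emulate UMI count data
# (negative-binomial noise, sparse baseline means) with planted clusters
# and marker genes, and embryo-like positional bin maps, so every pipeline
# stage is testable without any download.

#' Simulate negative-binomial counts with planted clusters
#'
#' Baseline per-gene means are drawn uniformly from
#' `[mean_range[1], mean_range[2]]`. Cells are split into `n_clusters`
#' groups (equal sizes, or one rare group of `rare_fraction` of the cells);
#' each cluster owns a disjoint block of `markers_per_cluster` marker genes
#' whose mean is multiplied by `2^log2fc` in that cluster. Counts are
#' negative binomial with dispersion `nb_dispersion`
#' (`size = 1/nb_dispersion`).
#'
#' @param n_cells,n_genes Matrix dimensions.
#' @param n_clusters Number of planted clusters (default 5).
#' @param markers_per_cluster Marker genes planted per cluster (default 50).
#' @param log2fc Marker fold change on the log2 scale (default 2).
#' @param nb_dispersion Negative-binomial dispersion (default 0.3).
#' @param rare_fraction If non-`NULL`, the last cluster holds this fraction
#'   of the cells and the rest are split evenly.
#' @param mean_range Baseline mean range (default `c(0.5, 2)`).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @return A list: `counts` (sparse cells-by-genes matrix), `truth`
#'   (`labels` tibble of `cell_id`/`cluster`, `marker_map` list of gene ids
#'   per cluster, `params`).
#' @export
simulate_counts <- function(n_cells = 1000, n_genes = 2000, n_clusters = 5,
                            markers_per_cluster = 50, log2fc = 2,
                            nb_dispersion = 0.3, rare_fraction = NULL,
                            mean_range = c(0.5, 2), seed = 1) {
  if (markers_per_cluster * n_clusters > n_genes) {
    abort("markers_per_cluster * n_clusters exceeds n_genes.")
  }
  if (n_clusters > n_cells) abort("more clusters than cells.")
  with_seed(seed, {
    if (is.null(rare_fraction)) {
      sizes <- rep(n_cells %/% n_clusters, n_clusters)
      sizes[seq_len(n_cells - sum(sizes))] <- sizes[seq_len(n_cells - sum(sizes))] + 1L
    } else {
      rare <- max(1L, as.integer(round(rare_fraction * n_cells)))
      rest <- n_cells - rare
      sizes <- rep(rest %/% (n_clusters - 1L), n_clusters - 1L)
      sizes[seq_len(rest - sum(sizes))] <- sizes[seq_len(rest - sum(sizes))] + 1L
      sizes <- c(sizes, rare)
    }
    labels <- rep(seq_len(n_clusters), sizes)
    base_mu <- runif(n_genes, mean_range[1], mean_range[2])
    marker_map <- lapply(seq_len(n_clusters), function(cl) {
      paste0("gene", (cl - 1L) * markers_per_cluster + seq_len(markers_per_cluster))
    })
    names(marker_map) <- as.character(seq_len(n_clusters))
    mu <- matrix(base_mu, n_cells, n_genes, byrow = TRUE)
    for (cl in seq_len(n_clusters)) {
      gidx <- (cl - 1L) * markers_per_cluster + seq_len(markers_per_cluster)
      mu[labels == cl, gidx] <- mu[labels == cl, gidx] * 2^log2fc
    }
    counts <- matrix(rnbinom(n_cells * n_genes, mu = as.vector(mu),
                             size = 1 / nb_dispersion),
                     n_cells, n_genes)
    dimnames(counts) <- list(paste0("cell", seq_len(n_cells)),
                             paste0("gene", seq_len(n_genes)))
    list(
      counts = as_count_matrix(counts),
      truth = list(
        labels = tibble(cell_id = rownames(counts), cluster = labels),
        marker_map = marker_map,
        params = list(n_cells = n_cells, n_genes = n_genes,
                      n_clusters = n_clusters,
                      markers_per_cluster = markers_per_cluster,
                      log2fc = log2fc, nb_dispersion = nb_dispersion,
                      rare_fraction = rare_fraction, seed = seed)
      )
    )
  })
}

#' Simulate an embryo-like positional bin map
#'
#' Bins are placed on an ellipse (half-axes 2 and 1). Each cluster owns a
#' contiguous arc and `genes_per_cluster` genes whose mapping score peaks
#' at the arc center with Gaussian falloff in angular distance, plus
#' Gaussian noise of standard deviation `noise_sd`.
#'
#' @param n_bins Number of positional bins (>= 10; default 300).
#' @param n_clusters Number of arcs/clusters (default 5).
#' @param genes_per_cluster Genes peaking in each arc (default 20).
#' @param noise_sd Additive score noise (default 0.1).
#' @param seed Integer seed.
#' @return A list: `binmap` (a `stardust_binmap`), `truth` (`arc_masks`
#'   logical bins-per-cluster matrix, `marker_map`, `params`).
#' @export
simulate_binmap <- function(n_bins = 300, n_clusters = 5,
                            genes_per_cluster = 20, noise_sd = 0.1,
                            seed = 1) {
  if (n_bins < 10) abort("`n_bins` must be at least 10.")
  with_seed(seed, {
    theta <- sort(runif(n_bins, 0, 2 * pi))
    coords <- cbind(x = 2 * cos(theta), y = sin(theta))
    rownames(coords) <- paste0("bin", seq_len(n_bins))
    arc_width <- 2 * pi / n_clusters
    centers <- (seq_len(n_clusters) - 0.5) * arc_width
    ang_dist <- function(a, b) {
      d <- abs(a - b) %% (2 * pi)
      pmin(d, 2 * pi - d)
    }
    sigma <- arc_width / 4
    scores <- matrix(0, n_clusters * genes_per_cluster, n_bins)
    gene_ids <- character(nrow(scores))
    marker_map <- list()
    for (cl in seq_len(n_clusters)) {
      shape <- exp(-ang_dist(theta, centers[cl])^2 / (2 * sigma^2))
      rows <- (cl - 1L) * genes_per_cluster + seq_len(genes_per_cluster)
      for (r in rows) {
        scores[r, ] <- shape + rnorm(n_bins, sd = noise_sd)
      }
      ids <- paste0("zgene", rows)
      gene_ids[rows] <- ids
      marker_map[[as.character(cl)]] <- ids
    }
    rownames(scores) <- gene_ids
    colnames(scores) <- rownames(coords)
    arc_masks <- vapply(seq_len(n_clusters), function(cl) {
      ang_dist(theta, centers[cl]) <= arc_width / 2
    }, logical(n_bins))
    colnames(arc_masks) <- as.character(seq_len(n_clusters))
    rownames(arc_masks) <- rownames(coords)
    list(
      binmap = binmap(scores, coords),
      truth = list(arc_masks = arc_masks, marker_map = marker_map,
                   params = list(n_bins = n_bins, n_clusters = n_clusters,
                                 genes_per_cluster = genes_per_cluster,
                                 noise_sd = noise_sd, seed = seed))
    )
  })
}
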