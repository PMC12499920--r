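#' Structure-preserving sampling proportion
#'
#' Exponential decay of the per-cluster sampling proportion in the cluster
#' size `s`: `p = p_l - exp(-s / k_scale) * (p_l - p_u)`. Small clusters are
#' sampled near the upper bound `p_u`, large clusters decay towards the
#' lower bound `p_l`, so rare populations are retained at a higher rate.
#'
#' @param s Cluster size(s), positive integer(s).
#' @param p_l Lower-bound proportion in (0, 1] (large-cluster limit).
#' @param p_u Upper-bound proportion in (0, 1] (small-cluster limit).
#' @param k_scale Positive scaling factor controlling the decay rate.
#' @return Sampling proportion(s), same length as `s`.
#' @export
sps_proportion <- function(s, p_l = 0.3, p_u = 0.9, k_scale = 500) {
  if (k_scale <= 0) abort("`k_scale` must be positive.")
  stopifnot(p_l > 0, p_l <= 1, p_u > 0, p_u <= 1, all(s >= 0))
  p_l - exp(-s / k_scale) * (p_l - p_u)
}

#' Structure-preserving subsampling of cells
#'
#' Builds a cell kNN graph in PC space, finds preliminary clusters with
#' modularity-based community detection, computes each cluster's sampling
#' proportion with [sps_proportion()], and samples cells without
#' replacement; every cluster contributes at least one cell. Per-cluster
#' sample counts use half-away-from-zero rounding, floored at 1.
#'
#' @param norm A `stardust_norm` object.
#' @param seed Integer seed controlling clustering and sampling.
#' @param p_l,p_u,k_scale Decay parameters; see [sps_proportion()].
#' @param k Neighbors for the preliminary kNN graph (default 20).
#' @param n_comp PCA components for the neighbor space (default 50; the
#'   preliminary clustering does not need the full component budget).
#' @return A `stardust_sps` list: `clusters` tibble (`cluster`, `size`,
#'   `proportion`, `n_sampled`), `sampled_cell_ids`, `leftover_cell_ids`,
#'   `params`.
#' @export
sps_subsample <- function(norm, seed = 1, p_l = 0.3, p_u = 0.9,
                          k_scale = 500, k = 20, n_comp = 50) {
  values <- norm_values(norm)
  if (nrow(values) < 2) abort("subsampling needs at least 2 cells.")
  pca <- compute_pca(norm, n_comp = min(n_comp, nrow(values) - 1L, ncol(values)),
                     seed = seed)
  edges <- build_cell_edges(pca, k = min(k, nrow(values) - 1L), seed = seed)
  ig <- igraph::graph_from_data_frame(
    as.data.frame(edges[, c("from", "to")]), directed = FALSE,
    vertices = rownames(values))
  comm <- with_seed(seed, igraph::cluster_louvain(ig))
  member <- igraph::membership(comm)
  member <- member[rownames(values)]
  sizes <- table(member)
  props <- sps_proportion(as.numeric(sizes), p_l = p_l, p_u = p_u,
                          k_scale = k_scale)
  n_sampled <- pmax(1L, as.integer(round_half_up(props * as.numeric(sizes))))
  n_sampled <- pmin(n_sampled, as.integer(sizes))
  sampled <- with_seed(child_seed(seed, 2L), {
    unlist(lapply(seq_along(sizes), function(i) {
      cl_cells <- names(member)[member == names(sizes)[i]]
      sample(cl_cells, n_sampled[i])
    }), use.names = FALSE)
  })
  sampled <- rownames(values)[rownames(values) %in% sampled]
  structure(list(
    clusters = tibble(cluster = as.integer(names(sizes)),
                      size = as.integer(sizes),
                      proportion = props, n_sampled = n_sampled),
    sampled_cell_ids = sampled,
    leftover_cell_ids = setdiff(rownames(values), sampled),
    params = list(seed = seed, p_l = p_l, p_u = p_u, k_scale = k_scale, k = k)
  ), class = "stardust_sps")
}

#' @export
print.stardust_sps <- function(x, ...) {
  cat("<stardust_sps> ", length(x$sampled_cell_ids), " of ",
      length(x$sampled_cell_ids) + length(x$leftover_cell_ids),
      " cells sampled across ", nrow(x$clusters), " preliminary clusters\n",
      sep = "")
  invisible(x)
}
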