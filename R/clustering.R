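#' DBSCAN clustering of layout coordinates
#'
#' Standard density-based clustering on the 2D embedding of the cells.
#' Points with at least `min_samples` neighbors within `eps` (the point
#' itself included) are core points; clusters are the connected components
#' of core points under eps-reachability, border points join a cluster of a
#' core neighbor, everything else is noise (label -1). Clusters are labeled
#' 1..K in order of first appearance.
#'
#' When `eps` is `NULL` it is set from the knee of the sorted
#' `min_samples`-nearest-neighbor distance curve (the point of maximum
#' distance to the chord connecting the curve's endpoints), a standard
#' automatic calibration.
#'
#' @param emb Embedding tibble; only rows with `node_type == "cell"` are
#'   clustered (a plain tibble of `node_id`, `x`, `y` also works).
#' @param eps Neighborhood radius; `NULL` for the k-distance knee default.
#' @param min_samples Core-point threshold (default 20).
#' @return A cluster-assignment tibble: `cell_id`, `cluster` (1..K, noise
#'   -1), `source` (`"dbscan"`); attribute `eps` records the radius used.
#' @export
dbscan_embed <- function(emb, eps = NULL, min_samples = 20) {
  if ("node_type" %in% names(emb)) emb <- emb[emb$node_type == "cell", ]
  pos <- as.matrix(emb[, c("x", "y")])
  n <- nrow(pos)
  if (n < min_samples) abort("fewer cells than `min_samples`.")
  if (is.null(eps)) eps <- knee_eps(pos, k = min_samples)
  if (eps <= 0) abort("`eps` must be positive.")
  labels <- dbscan_core(pos, eps = eps, min_pts = min_samples)
  out <- tibble(cell_id = emb$node_id, cluster = labels, source = "dbscan")
  attr(out, "eps") <- eps
  out
}

# k-distance knee: max perpendicular distance to the endpoint chord.
knee_eps <- function(pos, k) {
  k <- min(k, nrow(pos) - 1L)
  kd <- sort(FNN::get.knn(pos, k = k)$nn.dist[, k])
  n <- length(kd)
  if (n < 3 || kd[n] == kd[1]) return(max(kd[n], 1e-9))
  xs <- (seq_len(n) - 1) / (n - 1)
  ys <- (kd - kd[1]) / (kd[n] - kd[1])
  d <- abs(ys - xs) / sqrt(2)
  eps <- kd[which.max(d)]
  max(eps, 1e-9)
}

# Neighborhood lists within eps, computed blockwise to bound memory.
eps_neighbors <- function(pos, eps) {
  n <- nrow(pos)
  nb <- vector("list", n)
  block <- max(1L, as.integer(2e7 / n))
  q <- rowSums(pos^2)
  for (s in seq(1L, n, by = block)) {
    e <- min(n, s + block - 1L)
    d2 <- outer(q[s:e], q, "+") - 2 * pos[s:e, , drop = FALSE] %*% t(pos)
    hits <- d2 <= eps^2 + 1e-12
    for (i in seq_len(e - s + 1L)) nb[[s + i - 1L]] <- which(hits[i, ])
  }
  nb
}

# Classical DBSCAN via BFS over core points.
dbscan_core <- function(pos, eps, min_pts) {
  n <- nrow(pos)
  nb <- eps_neighbors(pos, eps)
  core <- vapply(nb, length, integer(1)) >= min_pts
  labels <- rep(NA_integer_, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is.na(labels[i]) || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[[i]]
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      if (is.na(labels[j])) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, nb[[j]][is.na(labels[nb[[j]]])])
      } else if (labels[j] == -1L) {
        labels[j] <- cl  # noise upgraded to border
      }
    }
  }
  labels[is.na(labels)] <- -1L
  labels
}

#' Post-hoc assignment of held-out cells
#'
#' Cells left out by subsampling are assigned to existing clusters: each
#' leftover cell queries its `k` nearest sampled cells in PC space and
#' takes the majority cluster among them (ties go to the cluster of the
#' single nearest neighbor). Its 2D coordinates are the mean of the
#' coordinates of those neighbors that belong to the assigned cluster.
#'
#' @param leftover_cells Character vector of held-out cell ids.
#' @param pca A `stardust_pca` whose scores cover sampled and leftover
#'   cells (or a plain score matrix).
#' @param sampled_labels Cluster-assignment tibble for the sampled cells.
#' @param emb Embedding tibble holding the sampled cells' coordinates.
#' @param k Neighbors to query (default 20; clamped to the sampled count
#'   with a warning).
#' @return A cluster-assignment tibble for the leftover cells: `cell_id`,
#'   `cluster`, `source` (`"posthoc"`), `x`, `y`.
#' @export
posthoc_assign <- function(leftover_cells, pca, sampled_labels, emb, k = 20) {
  if (length(leftover_cells) == 0) {
    return(tibble(cell_id = character(), cluster = integer(),
                  source = character(), x = numeric(), y = numeric()))
  }
  if (nrow(sampled_labels) == 0) abort("`sampled_labels` is empty.")
  if (length(intersect(leftover_cells, sampled_labels$cell_id))) {
    abort("leftover and sampled cell sets overlap.")
  }
  scores <- if (inherits(pca, "stardust_pca")) pca$scores else as.matrix(pca)
  if (k > nrow(sampled_labels)) {
    warn(paste0("k clamped from ", k, " to the sampled count ",
                nrow(sampled_labels), "."))
    k <- nrow(sampled_labels)
  }
  samp <- sampled_labels$cell_id
  nn <- FNN::get.knnx(scores[samp, , drop = FALSE],
                      scores[leftover_cells, , drop = FALSE], k = k)$nn.index
  lab <- setNames(sampled_labels$cluster, samp)
  coords <- as.matrix(emb[match(samp, emb$node_id), c("x", "y")])
  out <- lapply(seq_along(leftover_cells), function(i) {
    nbr <- nn[i, ]
    nlab <- lab[samp[nbr]]
    tb <- table(nlab)
    winners <- names(tb)[tb == max(tb)]
    cl <- if (length(winners) == 1) as.integer(winners) else as.integer(nlab[[1]])
    use <- nbr[nlab == cl]
    xy <- colMeans(coords[use, , drop = FALSE])
    tibble(cell_id = leftover_cells[[i]], cluster = cl, source = "posthoc",
           x = xy[[1]], y = xy[[2]])
  })
  dplyr::bind_rows(out)
}
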