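#' Normalized mutual information between two labelings
#'
#' Mutual information of the two label vectors normalized by the
#' arithmetic mean of their entropies. When both sides are a single
#' cluster the value is defined as 1; when only one side is degenerate the
#' value is 0.
#'
#' @param a,b Label vectors over the same items (any atomic type).
#' @return NMI in \[0, 1\].
#' @export
nmi <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- sum(tab)
  pij <- tab / n
  pi <- rowSums(pij); pj <- colSums(pij)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  ha <- ent(pi); hb <- ent(pj)
  if (ha == 0 && hb == 0) return(1)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi, pj)[nz]))
  denom <- (ha + hb) / 2
  if (denom == 0) 0 else mi / denom
}

#' Adjusted Rand index between two labelings
#'
#' Pair-counting Rand index adjusted for chance under the permutation
#' model.
#'
#' @inheritParams nmi
#' @return ARI in \[-1, 1\]; 1 for identical partitions.
#' @export
ari <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- sum(tab)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_i <- sum(ch2(rowSums(tab)))
  sum_j <- sum(ch2(colSums(tab)))
  expected <- sum_i * sum_j / ch2(n)
  max_idx <- (sum_i + sum_j) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

#' Mean silhouette of a clustering in 2D
#'
#' For each point, `a` is its mean distance to its own cluster's other
#' members and `b` the smallest mean distance to another cluster; the
#' silhouette is `(b - a) / max(a, b)`. Members of singleton clusters
#' contribute 0. Euclidean distances in the supplied coordinate space.
#'
#' @param coords Matrix or tibble of coordinates (columns `x`, `y` used if
#'   present, otherwise all numeric columns).
#' @param labels Cluster labels; noise (-1) points are dropped before
#'   scoring.
#' @return Mean silhouette in \[-1, 1\].
#' @export
silhouette_score <- function(coords, labels) {
  if (is.data.frame(coords)) {
    cols <- intersect(c("x", "y"), names(coords))
    coords <- as.matrix(if (length(cols) == 2) coords[, cols]
                        else coords[, vapply(coords, is.numeric, logical(1))])
  }
  keep <- labels != -1
  coords <- coords[keep, , drop = FALSE]
  labels <- labels[keep]
  uc <- unique(labels)
  if (length(uc) < 2) abort("silhouette needs at least 2 clusters.")
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  s <- numeric(n)
  idx_by <- split(seq_len(n), labels)
  for (i in seq_len(n)) {
    own <- idx_by[[as.character(labels[i])]]
    if (length(own) == 1) { s[i] <- 0; next }
    a_i <- sum(d[i, own]) / (length(own) - 1)
    b_i <- min(vapply(idx_by[names(idx_by) != as.character(labels[i])],
                      function(ix) mean(d[i, ix]), numeric(1)))
    m <- max(a_i, b_i)
    s[i] <- if (m == 0) 0 else (b_i - a_i) / m
  }
  mean(s)
}

#' Clustering quality report
#'
#' Computes NMI and ARI against a reference labeling (when given) and the
#' silhouette of the clustering in its 2D space.
#'
#' @param emb Embedding tibble of the cells (`node_id`, `x`, `y`).
#' @param labels Cluster-assignment tibble (`cell_id`, `cluster`).
#' @param truth Optional reference tibble (`cell_id`, `cluster`) or vector
#'   named by cell id.
#' @return One-row tibble: `n_clusters`, `silhouette`, and `nmi`/`ari`
#'   when `truth` is supplied.
#' @export
evaluate_clustering <- function(emb, labels, truth = NULL) {
  if ("node_type" %in% names(emb)) emb <- emb[emb$node_type == "cell", ]
  lab <- labels$cluster[match(emb$node_id, labels$cell_id)]
  res <- tibble(
    n_clusters = length(setdiff(unique(lab), -1L)),
    silhouette = silhouette_score(emb, lab)
  )
  if (!is.null(truth)) {
    tr <- if (is.data.frame(truth)) {
      setNames(truth$cluster, truth$cell_id)
    } else truth
    tr <- tr[emb$node_id]
    res$nmi <- nmi(lab, tr)
    res$ari <- ari(lab, tr)
  }
  res
}
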