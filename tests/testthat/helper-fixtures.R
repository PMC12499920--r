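# Shared fixtures, built in code and cached for the session so the heavy
# pipeline runs once.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Standard synthetic fixture: 1000 cells, 2000 genes, 5 clusters,
# 50 markers/cluster, log2fc 2, NB dispersion 0.3, seed 7.
std_sim <- function() {
  cached("std_sim", simulate_counts(
    n_cells = 1000, n_genes = 2000, n_clusters = 5,
    markers_per_cluster = 50, log2fc = 2, nb_dispersion = 0.3, seed = 7))
}

std_fit <- function() {
  cached("std_fit", run_stardust(std_sim()$counts,
                                 stardust_config(seed = 7, sps = FALSE)))
}

# Small fixture for fast pipeline-level tests.
small_sim <- function() {
  cached("small_sim", simulate_counts(
    n_cells = 300, n_genes = 600, n_clusters = 5,
    markers_per_cluster = 30, log2fc = 2, nb_dispersion = 0.3, seed = 11))
}

small_fit <- function() {
  cached("small_fit", run_stardust(small_sim()$counts,
                                   stardust_config(seed = 11, sps = FALSE)))
}

# Fraction of projected markers (top `per` per cluster) whose nearest
# cluster centroid, in the space of `cell_emb`, is their own cluster.
colocation_rate <- function(gene_coords, cell_emb, labels, top, per = 5) {
  lab <- labels$cluster[match(cell_emb$node_id, labels$cell_id)]
  keep <- lab != -1
  cents <- stats::aggregate(cbind(x, y) ~ cluster,
                            data = data.frame(x = cell_emb$x[keep],
                                              y = cell_emb$y[keep],
                                              cluster = lab[keep]),
                            FUN = mean)
  tp <- top[top$rank_in_cluster <= per, ]
  gc <- merge(as.data.frame(gene_coords), as.data.frame(tp),
              by.x = c("node_id", "cluster"), by.y = c("gene_id", "cluster"))
  hits <- vapply(seq_len(nrow(gc)), function(i) {
    d <- sqrt((cents$x - gc$x[i])^2 + (cents$y - gc$y[i])^2)
    cents$cluster[which.min(d)] == gc$cluster[i]
  }, logical(1))
  mean(hits)
}

# Two n-node cliques joined by a single edge, as a pure cell-cell graph.
two_clique_graph <- function(n = 10) {
  ids <- c(paste0("a", seq_len(n)), paste0("b", seq_len(n)))
  cl <- function(p) t(utils::combn(p, 2))
  pairs <- rbind(cl(ids[1:n]), cl(ids[(n + 1):(2 * n)]),
                 c(ids[1], ids[n + 1]))
  edges <- tibble::tibble(from = pmin(pairs[, 1], pairs[, 2]),
                          to = pmax(pairs[, 1], pairs[, 2]),
                          class = "cell-cell")
  no_genes <- tibble::tibble(from = character(), to = character(),
                             class = character())
  cell_gene_graph(edges, no_genes, cell_ids = ids, gene_ids = character())
}

mean_intra_inter <- function(emb, n = 10) {
  pos <- as.matrix(emb[, c("x", "y")])
  grp <- substr(emb$node_id, 1, 1)
  d <- as.matrix(stats::dist(pos))
  same <- outer(grp, grp, "==") & upper.tri(d)
  diff <- outer(grp, grp, "!=") & upper.tri(d)
  c(intra = mean(d[same]), inter = mean(d[diff]))
}
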