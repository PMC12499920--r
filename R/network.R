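#' Principal component analysis of the normalized expression
#'
#' Centered (unscaled) PCA of the log-normalized matrix. The number of
#' components is clamped to `min(n_comp, cells - 1, genes)`. Small matrices
#' use an exact SVD; above `exact_max` cells a seeded randomized solver
#' (irlba) is used so results stay deterministic.
#'
#' @param norm A `stardust_norm` object or cells-by-genes numeric matrix.
#' @param n_comp Number of components requested (default 500).
#' @param seed Seed for the randomized solver (default 1).
#' @param exact_max Cell count up to which the exact solver is used
#'   (default 5000).
#' @return A `stardust_pca` list: `scores` (cells x n_comp), `loadings`
#'   (genes x n_comp, unit-norm columns), `center` (gene means),
#'   `explained_variance`, `n_comp`.
#' @export
compute_pca <- function(norm, n_comp = 500, seed = 1, exact_max = 5000) {
  values <- norm_values(norm)
  n <- nrow(values); g <- ncol(values)
  if (n < 2) abort("PCA needs at least 2 cells.")
  k <- as.integer(min(n_comp, n - 1L, g))
  if (k < n_comp) {
    inform(paste0("n_comp clamped from ", n_comp, " to ", k, "."))
  }
  dense <- as.matrix(values)
  center <- colMeans(dense)
  if (all(apply(dense, 2, var) == 0)) abort("degenerate matrix: zero variance in every gene.")
  if (n <= exact_max) {
    p <- prcomp(dense, center = TRUE, scale. = FALSE, rank. = k)
    scores <- p$x[, seq_len(k), drop = FALSE]
    loadings <- p$rotation[, seq_len(k), drop = FALSE]
    ev <- p$sdev[seq_len(k)]^2
  } else {
    p <- with_seed(seed, irlba::prcomp_irlba(dense, n = k, center = TRUE,
                                             scale. = FALSE))
    scores <- p$x
    loadings <- p$rotation
    ev <- p$sdev^2
    rownames(scores) <- rownames(dense)
    rownames(loadings) <- colnames(dense)
  }
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, loadings = loadings, center = center,
                 explained_variance = ev, n_comp = k),
            class = "stardust_pca")
}

#' @export
print.stardust_pca <- function(x, ...) {
  cat("<stardust_pca> ", nrow(x$scores), " cells, ", x$n_comp,
      " components\n", sep = "")
  invisible(x)
}

# Project held-out cells into an existing PC space.
project_pca <- function(pca, values) {
  dense <- as.matrix(values)
  sweep(dense, 2, pca$center[colnames(dense)]) %*%
    pca$loadings[colnames(dense), , drop = FALSE]
}

#' Select genes by PCA loadings
#'
#' Ranks genes by their maximum absolute loading across the retained
#' principal components and returns the top `n_genes`.
#'
#' @param pca A `stardust_pca` object.
#' @param n_genes Number of genes to select (default 500).
#' @return A gene-selection tibble: `gene_id`, `method` (`"pca_loading"`),
#'   `score`, ordered by decreasing score.
#' @export
pca_gene_selection <- function(pca, n_genes = 500) {
  score <- apply(abs(pca$loadings), 1, max)
  if (n_genes > length(score)) abort("n_genes exceeds the number of genes.")
  ord <- order(-score, names(score), method = "radix")
  sel <- head(ord, n_genes)
  tibble(gene_id = names(score)[sel], method = "pca_loading",
         score = unname(score[sel]))
}

#' Cell-cell nearest-neighbor edges
#'
#' Connects each cell to its `k` nearest cells by Euclidean distance in PC
#' space. Directed kNN relations are converted to undirected unit-weight
#' edges (mutuality is not required). Below `exact_max` cells an exact
#' search (FNN) is used; above it a seeded Annoy index (locality-sensitive
#' approximate search) keeps construction near-linear.
#'
#' @param pca A `stardust_pca` object (or a numeric score matrix).
#' @param k Number of neighbors per cell (default 20).
#' @param exact Force exact search regardless of size (default `NULL`:
#'   exact below `exact_max` cells).
#' @param exact_max Cell count up to which exact search is the default
#'   (default 2000).
#' @param n_trees Annoy forest size for the approximate index (default 50).
#' @param seed Seed for the approximate index (default 1).
#' @return Edge tibble: `from`, `to` (cell ids), `class` (`"cell-cell"`).
#' @export
build_cell_edges <- function(pca, k = 20, exact = NULL, exact_max = 2000,
                             n_trees = 50, seed = 1) {
  scores <- if (inherits(pca, "stardust_pca")) pca$scores else as.matrix(pca)
  n <- nrow(scores)
  if (k >= n) abort(paste0("k (", k, ") must be smaller than the number of cells (", n, ")."))
  exact <- exact %||% (n <= exact_max)
  if (exact) {
    nn <- FNN::get.knn(scores, k = k)$nn.index
  } else {
    ann <- methods::new(RcppAnnoy::AnnoyEuclidean, ncol(scores))
    ann$setSeed(as.integer(seed))
    for (i in seq_len(n)) ann$addItem(i - 1L, scores[i, ])
    ann$build(as.integer(n_trees))
    nn <- t(vapply(seq_len(n), function(i) {
      res <- ann$getNNsByItem(i - 1L, k + 1L)
      res <- res[res != i - 1L]
      head(res, k) + 1L
    }, integer(k)))
  }
  ids <- rownames(scores)
  from <- rep(seq_len(n), each = k)
  to <- as.integer(t(nn))
  undirected_unique_edges(ids[from], ids[to], class = "cell-cell")
}

# Deduplicate undirected pairs, drop self loops.
undirected_unique_edges <- function(a, b, class) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  keep <- lo != hi
  key <- paste(lo[keep], hi[keep], sep = "\r")
  dup <- duplicated(key)
  tibble(from = lo[keep][!dup], to = hi[keep][!dup], class = class)
}

#' Gene-cell edges by top normalized expression
#'
#' Connects each selected gene to the `n` cells where its normalized (log)
#' expression is highest; ties are broken by the order of the cell ids in
#' the matrix, so the construction is deterministic.
#'
#' @param norm A `stardust_norm` object.
#' @param genes A gene-selection tibble (or character vector of gene ids).
#' @param n Number of cells each gene connects to (default 10).
#' @return Edge tibble: `from` (cell id), `to` (gene id), `class`
#'   (`"cell-gene"`).
#' @export
build_gene_edges <- function(norm, genes, n = 10) {
  values <- norm_values(norm)
  gene_ids <- if (is.character(genes)) genes else genes$gene_id
  missing <- setdiff(gene_ids, colnames(values))
  if (length(missing)) {
    abort(paste0("genes absent from the matrix: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  n_eff <- min(n, nrow(values))
  cells <- rownames(values)
  pieces <- lapply(gene_ids, function(g) {
    expr <- values[, g]
    top <- head(order(-as.numeric(expr), seq_along(expr), method = "radix"), n_eff)
    tibble(from = cells[top], to = g, class = "cell-gene")
  })
  dplyr::bind_rows(pieces)
}

#' Rank-decayed gene-cell edges for the final pass
#'
#' In the final co-embedding pass each cluster-specific gene at
#' within-cluster rank `i` (1-20) is connected to `p = 5 - ceiling(i/10)`
#' cells of its own cluster, chosen as the top-`p` cells of that cluster by
#' the gene's normalized expression. Higher-quality markers therefore
#' attach to more cells.
#'
#' @param markers A marker table from [top_markers()] (columns `cluster`,
#'   `gene_id`, `rank_in_cluster`).
#' @param labels A cluster-assignment tibble (`cell_id`, `cluster`).
#' @param norm A `stardust_norm` object.
#' @return Edge tibble: `from` (cell id), `to` (gene id), `class`
#'   (`"cell-gene"`).
#' @export
build_gene_edges_pass4 <- function(markers, labels, norm) {
  values <- norm_values(norm)
  labels <- labels[labels$cluster != -1, ]
  pieces <- vector("list", nrow(markers))
  for (r in seq_len(nrow(markers))) {
    cl <- markers$cluster[[r]]
    g <- markers$gene_id[[r]]
    i <- markers$rank_in_cluster[[r]]
    p <- 5L - as.integer(ceiling(i / 10))
    cells <- labels$cell_id[labels$cluster == cl]
    if (length(cells) < p) {
      warn(paste0("cluster ", cl, " has fewer than ", p,
                  " cells; connecting gene ", g, " to all of them."))
      p <- length(cells)
    }
    expr <- as.numeric(values[cells, g])
    top <- head(order(-expr, seq_along(expr), method = "radix"), p)
    pieces[[r]] <- tibble(from = cells[top], to = g, class = "cell-gene")
  }
  dplyr::bind_rows(pieces)
}

#' Assemble and validate a cell-gene nearest-neighbor network
#'
#' The network is heterogeneous with typed nodes (cell or gene) and
#' unit-weight undirected edges of exactly two legal classes: cell-cell and
#' cell-gene. Gene-gene pairs, self loops and duplicate edges are rejected.
#'
#' @param cell_edges Edge tibble from [build_cell_edges()].
#' @param gene_edges Edge tibble from [build_gene_edges()] or
#'   [build_gene_edges_pass4()].
#' @param cell_ids Character vector of all cell node ids.
#' @param gene_ids Character vector of all gene node ids.
#' @return A `stardust_graph` list: `nodes` tibble (`node_id`, `node_type`)
#'   and `edges` tibble (`from`, `to`, `class`).
#' @export
cell_gene_graph <- function(cell_edges, gene_edges, cell_ids, gene_ids) {
  nodes <- dplyr::bind_rows(
    tibble(node_id = cell_ids, node_type = "cell"),
    tibble(node_id = gene_ids, node_type = "gene")
  )
  edges <- dplyr::bind_rows(cell_edges, gene_edges)
  g <- structure(list(nodes = nodes, edges = edges), class = "stardust_graph")
  validate_graph(g)
}

#' Validate a cell-gene network
#'
#' @param graph A `stardust_graph`.
#' @return The graph, invisibly returned after validation; errors on any
#'   illegal structure (gene-gene edge, self loop, duplicate edge, unknown
#'   node, duplicate node id).
#' @export
validate_graph <- function(graph) {
  nodes <- graph$nodes; edges <- graph$edges
  if (anyDuplicated(nodes$node_id)) abort("duplicate node ids (a cell and gene share an id?).")
  type <- setNames(nodes$node_type, nodes$node_id)
  if (!all(edges$from %in% nodes$node_id) || !all(edges$to %in% nodes$node_id)) {
    abort("edge endpoint not present among graph nodes.")
  }
  tf <- type[edges$from]; tt <- type[edges$to]
  if (any(tf == "gene" & tt == "gene")) abort("illegal gene-gene edge in cell-gene network.")
  if (any(edges$from == edges$to)) abort("self loop in cell-gene network.")
  lo <- pmin(edges$from, edges$to); hi <- pmax(edges$from, edges$to)
  if (anyDuplicated(paste(lo, hi, sep = "\r"))) abort("duplicate edge in cell-gene network.")
  cls <- ifelse(tf == "cell" & tt == "cell", "cell-cell", "cell-gene")
  if (!all(edges$class == cls)) abort("edge class inconsistent with endpoint types.")
  graph
}

#' @export
print.stardust_graph <- function(x, ...) {
  nt <- table(x$nodes$node_type)
  ec <- table(x$edges$class)
  cat("<stardust_graph> ", nt[["cell"]] %||% 0, " cells + ",
      nt["gene"] %||% 0, " genes; ",
      ec["cell-cell"] %||% 0, " cell-cell and ",
      ec["cell-gene"] %||% 0, " cell-gene unit edges\n", sep = "")
  invisible(x)
}

as_igraph <- function(graph) {
  ig <- igraph::graph_from_data_frame(
    graph$edges[, c("from", "to")], directed = FALSE,
    vertices = as.data.frame(graph$nodes)
  )
  igraph::E(ig)$weight <- 1
  ig
}

#' Export a cell-gene network
#'
#' Writes GraphML (via igraph) or a two-column edge list plus a node-type
#' sidecar (`<path>.nodes.tsv`); the edge-list form round-trips bit-exactly
#' through [import_graph()].
#'
#' @param graph A `stardust_graph`.
#' @param path Output path; `.graphml` selects GraphML, anything else the
#'   edge-list form.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path) {
  if (grepl("\\.graphml$", path)) {
    igraph::write_graph(as_igraph(graph), path, format = "graphml")
  } else {
    write.table(as.data.frame(graph$edges[, c("from", "to")]), path,
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(graph$nodes), paste0(path, ".nodes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Import a cell-gene network written by [export_graph()]
#'
#' @param path Path to the edge-list file (with its `.nodes.tsv` sidecar).
#' @return A validated `stardust_graph`.
#' @export
import_graph <- function(path) {
  edges <- as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                                colClasses = "character"))
  nodes <- as_tibble(read.delim(paste0(path, ".nodes.tsv"), sep = "\t",
                                stringsAsFactors = FALSE,
                                colClasses = "character"))
  type <- setNames(nodes$node_type, nodes$node_id)
  cls <- ifelse(type[edges$from] == "cell" & type[edges$to] == "cell",
                "cell-cell", "cell-gene")
  g <- structure(list(nodes = nodes,
                      edges = tibble(from = edges$from, to = edges$to,
                                     class = unname(cls))),
                 class = "stardust_graph")
  validate_graph(g)
}
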