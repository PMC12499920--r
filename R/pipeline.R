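#' Pipeline configuration
#'
#' Collects every tunable of the four-pass co-embedding pipeline with its
#' default. All seeds used downstream are derived deterministically from
#' `seed`.
#'
#' @param seed Master integer seed (default 1).
#' @param n_comp PCA components (default 500, clamped to the data).
#' @param k Cell-cell neighbors (default 20).
#' @param n_gene_cells Cells each gene connects to in passes 1-3
#'   (default 10).
#' @param genes_per_pass Gene-set size for passes 1-3 (default 500).
#' @param top_markers_n Markers per cluster for the final pass
#'   (default 20).
#' @param p_adj_max,lfc_min DE filters for pass 2-3 gene selection
#'   (defaults 0.5 and 1.2, both exclusive; note that 0.05 is the
#'   conventional adjusted-p cutoff, 0.5 is this pipeline's permissive
#'   default).
#' @param min_samples DBSCAN core threshold (default 20).
#' @param eps DBSCAN radius; `NULL` = k-distance-knee default.
#' @param K Neighbors for the gene-projection KNN regression (default 5).
#' @param edge_cut Layout edge-cutting strength (default 0.8).
#' @param layout_backend `"openord"` or `"drl"`.
#' @param layout_iter Iteration budget of the annealing schedule
#'   (default 600).
#' @param sps Enable structure-preserving subsampling (default `TRUE`;
#'   skipped regardless when the dataset has at most `sps_threshold`
#'   cells).
#' @param sps_threshold Cell count at or below which subsampling is
#'   skipped (default 5000).
#' @param sps_pl,sps_pu,sps_k SPS decay parameters (defaults 0.3, 0.9,
#'   500).
#' @return A `stardust_config` list.
#' @export
stardust_config <- function(seed = 1, n_comp = 500, k = 20, n_gene_cells = 10,
                            genes_per_pass = 500, top_markers_n = 20,
                            p_adj_max = 0.5, lfc_min = 1.2, min_samples = 20,
                            eps = NULL, K = 5, edge_cut = 0.8,
                            layout_backend = c("openord", "drl"),
                            layout_iter = 600, sps = TRUE,
                            sps_threshold = 5000, sps_pl = 0.3, sps_pu = 0.9,
                            sps_k = 500) {
  structure(list(
    seed = as.integer(seed), n_comp = n_comp, k = k,
    n_gene_cells = n_gene_cells, genes_per_pass = genes_per_pass,
    top_markers_n = top_markers_n, p_adj_max = p_adj_max, lfc_min = lfc_min,
    min_samples = min_samples, eps = eps, K = K, edge_cut = edge_cut,
    layout_backend = match.arg(layout_backend), layout_iter = layout_iter,
    sps = sps, sps_threshold = sps_threshold, sps_pl = sps_pl,
    sps_pu = sps_pu, sps_k = sps_k
  ), class = "stardust_config")
}

#' Run the four-pass cell-gene co-embedding pipeline
#'
#' Orchestrates preprocessing, optional structure-preserving subsampling,
#' and four network/layout passes: pass 1 selects genes by PCA loadings;
#' passes 2 and 3 rewire the network with differentially expressed genes
#' from the previous pass's clusters; pass 4 rebuilds the network from the
#' top per-cluster markers with rank-decayed connectivity and serves only
#' to place genes, which are then mapped back into the pass-3 space by
#' per-cluster KNN regression. Final cell coordinates and cluster labels
#' come from pass 3 (held-out cells are assigned post hoc); gene
#' coordinates come from the projection.
#'
#' @param counts Cells-by-genes count matrix (or anything
#'   [as_count_matrix()] accepts).
#' @param config A [stardust_config()].
#' @return A `stardust_fit` list: `cell_coords`, `gene_coords`, `labels`,
#'   `markers` (full pass-3 ranking), `top_markers`, `pass_log`, `config`,
#'   `pca`, `embeddings` (per-pass layouts).
#' @export
run_stardust <- function(counts, config = stardust_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  seed <- config$seed
  counts <- stage("preprocess", {
    counts <- filter_genes(filter_cells(as_count_matrix(counts)))
    if (nrow(counts) < 2) abort("fewer than 2 cells after filtering.")
    counts
  })
  norm <- stage("normalize", normalize_log(counts))
  all_cells <- rownames(norm$values)

  do_sps <- config$sps && length(all_cells) > config$sps_threshold
  plan <- NULL
  if (do_sps) {
    plan <- stage("sps", sps_subsample(norm, seed = child_seed(seed, 1L),
                                       p_l = config$sps_pl, p_u = config$sps_pu,
                                       k_scale = config$sps_k, k = config$k))
    sampled <- plan$sampled_cell_ids
  } else {
    sampled <- all_cells
  }
  leftover <- setdiff(all_cells, sampled)
  norm_s <- structure(list(values = norm$values[sampled, , drop = FALSE],
                           median_total = norm$median_total),
                      class = "stardust_norm")

  pca <- stage("pca", compute_pca(norm_s, n_comp = config$n_comp,
                                  seed = child_seed(seed, 2L)))
  scores_all <- pca$scores
  if (length(leftover)) {
    scores_all <- rbind(scores_all,
                        project_pca(pca, norm$values[leftover, , drop = FALSE]))
  }
  pca_all <- structure(list(scores = scores_all, loadings = pca$loadings,
                            center = pca$center,
                            explained_variance = pca$explained_variance,
                            n_comp = pca$n_comp), class = "stardust_pca")
  cell_edges <- stage("cell_edges",
                      build_cell_edges(pca, k = min(config$k, nrow(pca$scores) - 1L),
                                       seed = child_seed(seed, 3L)))

  pca_sel <- pca_gene_selection(pca, min(config$genes_per_pass,
                                         nrow(pca$loadings)))
  genes <- pca_sel
  schedule <- openord_schedule(n_iter = config$layout_iter)
  embeddings <- list()
  labels_by_pass <- list()
  markers <- NULL
  pass_log <- list()
  prev_labels <- NULL

  for (pass in 1:3) {
    gene_edges <- stage("gene_edges",
                        build_gene_edges(norm_s, genes, n = config$n_gene_cells))
    graph <- stage("graph", cell_gene_graph(cell_edges, gene_edges,
                                            cell_ids = sampled,
                                            gene_ids = unique(genes$gene_id)))
    emb <- stage("layout", layout_graph(graph, seed = child_seed(seed, 10L + pass),
                                        edge_cut = config$edge_cut,
                                        schedule = schedule,
                                        backend = config$layout_backend))
    embeddings[[pass]] <- emb
    lab <- stage("dbscan", dbscan_embed(emb, eps = config$eps,
                                        min_samples = min(config$min_samples,
                                                          length(sampled) - 1L)))
    if (length(leftover)) {
      ph <- stage("posthoc", posthoc_assign(leftover, pca_all, lab, emb,
                                            k = config$k))
      lab_all <- dplyr::bind_rows(lab, ph[, c("cell_id", "cluster", "source")])
    } else {
      ph <- NULL
      lab_all <- lab
    }
    labels_by_pass[[pass]] <- lab_all
    if (pass == 3 && !is.null(ph)) attr(labels_by_pass[[3]], "posthoc") <- ph

    n_cl <- length(setdiff(unique(lab$cluster), -1L))
    ari_prev <- if (!is.null(prev_labels)) {
      ari(prev_labels$cluster[match(all_cells, prev_labels$cell_id)],
          lab_all$cluster[match(all_cells, lab_all$cell_id)])
    } else NA_real_
    prev_labels <- lab_all

    new_markers <- NULL
    if (n_cl >= 2) {
      new_markers <- stage("rank_genes", rank_genes(norm, lab_all))
    }
    pass_log[[pass]] <- tibble(pass = pass, n_genes = nrow(genes),
                               n_clusters = n_cl, ari_prev = ari_prev)
    if (pass < 3) {
      if (is.null(new_markers)) {
        warn(paste0("pass ", pass, " produced fewer than 2 clusters; ",
                    "keeping the previous gene selection."))
      } else {
        markers <- new_markers
        genes <- select_pass_genes(new_markers, p_adj_max = config$p_adj_max,
                                   lfc_min = config$lfc_min,
                                   cap = config$genes_per_pass,
                                   fallback = pca_sel)
      }
    } else {
      if (is.null(new_markers)) {
        abort("stage 'rank_genes' failed: pass 3 produced fewer than 2 clusters.")
      }
      markers <- new_markers
    }
  }

  labels3 <- labels_by_pass[[3]]
  top <- stage("top_markers", top_markers(markers, config$top_markers_n))

  # pass 4: rank-decayed gene edges within clusters of sampled cells
  lab3_sampled <- labels3[labels3$cell_id %in% sampled, ]
  gene_edges4 <- stage("gene_edges_pass4",
                       build_gene_edges_pass4(
                         top[top$gene_id %in% colnames(norm_s$values), ],
                         lab3_sampled, norm_s))
  graph4 <- stage("graph", cell_gene_graph(cell_edges, gene_edges4,
                                           cell_ids = sampled,
                                           gene_ids = unique(gene_edges4$to)))
  emb4 <- stage("layout", layout_graph(graph4, seed = child_seed(seed, 14L),
                                       edge_cut = config$edge_cut,
                                       schedule = schedule,
                                       backend = config$layout_backend))
  embeddings[[4]] <- emb4
  pass_log[[4]] <- tibble(pass = 4L, n_genes = length(unique(gene_edges4$to)),
                          n_clusters = NA_integer_, ari_prev = NA_real_)

  gene_coords <- stage("project_genes",
                       project_genes(emb4, embeddings[[3]], lab3_sampled,
                                     top, K = config$K))

  emb3 <- embeddings[[3]]
  cell_coords <- emb3[emb3$node_type == "cell", ]
  ph3 <- attr(labels3, "posthoc")
  if (!is.null(ph3)) {
    cell_coords <- dplyr::bind_rows(
      cell_coords,
      tibble(node_id = ph3$cell_id, node_type = "cell", x = ph3$x, y = ph3$y))
  }

  structure(list(
    cell_coords = cell_coords,
    gene_coords = gene_coords,
    labels = labels3,
    markers = markers,
    top_markers = top,
    pass_log = dplyr::bind_rows(pass_log),
    config = config,
    sps_plan = plan,
    pca = pca_all,
    embeddings = embeddings
  ), class = "stardust_fit")
}

#' @export
print.stardust_fit <- function(x, ...) {
  cat("<stardust_fit> ", nrow(x$cell_coords), " cells, ",
      nrow(x$gene_coords), " projected genes, ",
      length(setdiff(unique(x$labels$cluster), -1L)), " clusters\n", sep = "")
  print(x$pass_log)
  invisible(x)
}

#' Project final-pass genes into the pass-3 cell space
#'
#' Per cluster, a K-nearest-neighbor regression is fit from the cluster's
#' cells: predictors are the cells' final-pass (pass-4) 2D coordinates and
#' responses their pass-3 coordinates (each response dimension fit
#' individually). The model is applied to the cluster's genes' pass-4
#' coordinates, yielding gene positions in the pass-3 space. A KNN
#' prediction is the mean response of the K nearest training points, so
#' every gene lands inside the convex hull of its cluster's cells.
#'
#' @param pass4 Embedding tibble of the final pass (cells + genes).
#' @param pass3 Embedding tibble of the third pass (responses).
#' @param labels Cluster-assignment tibble for cells present in both
#'   embeddings.
#' @param markers Marker tibble naming each gene's cluster (a gene placed
#'   for several clusters keeps its best rank).
#' @param K Regression neighbors (default 5; clamped per cluster with a
#'   warning when a cluster has fewer cells).
#' @return Embedding tibble of genes in pass-3 space: `node_id`,
#'   `node_type` (`"gene"`), `x`, `y`, `cluster`.
#' @export
project_genes <- function(pass4, pass3, labels, markers, K = 5) {
  knn_project(pass4, pass3, labels, markers, K)
}

#' Project final-pass genes onto an external embedding
#'
#' Same per-cluster KNN regression as [project_genes()], but the response
#' coordinates come from an externally computed embedding of the cells
#' (e.g. UMAP); each external dimension is treated individually as the
#' decision variable. Genes are placed in the external embedding's space.
#'
#' @param ext External embedding tibble covering every cell of `pass4`
#'   (`node_id`, `x`, `y`).
#' @inheritParams project_genes
#' @return Embedding tibble of genes in the external space.
#' @export
project_genes_external <- function(ext, pass4, labels, markers, K = 5) {
  cells4 <- pass4$node_id[pass4$node_type == "cell"]
  cells4 <- intersect(cells4, labels$cell_id)
  missing <- setdiff(cells4, ext$node_id)
  if (length(missing)) {
    abort(paste0("cells missing from the external embedding: ",
                 paste(head(missing, 10), collapse = ", "),
                 if (length(missing) > 10) ", ..." else ""))
  }
  knn_project(pass4, ext, labels, markers, K)
}

knn_project <- function(pred_emb, resp_emb, labels, markers, K) {
  pe <- pred_emb
  cells <- pe$node_id[pe$node_type == "cell"]
  genes_avail <- pe$node_id[pe$node_type == "gene"]
  pred_pos <- as.matrix(pe[, c("x", "y")])
  rownames(pred_pos) <- pe$node_id
  resp_pos <- as.matrix(resp_emb[, c("x", "y")])
  rownames(resp_pos) <- resp_emb$node_id
  mk <- markers[markers$gene_id %in% genes_avail, ]
  mk <- mk[order(mk$rank_in_cluster), ]
  mk <- mk[!duplicated(mk$gene_id), ]
  out <- lapply(sort(unique(mk$cluster)), function(cl) {
    cl_cells <- intersect(labels$cell_id[labels$cluster == cl],
                          intersect(cells, rownames(resp_pos)))
    cl_genes <- mk$gene_id[mk$cluster == cl]
    if (length(cl_cells) == 0 || length(cl_genes) == 0) return(NULL)
    k_eff <- K
    if (length(cl_cells) < K) {
      warn(paste0("cluster ", cl, " has ", length(cl_cells),
                  " cells; K clamped to that."))
      k_eff <- length(cl_cells)
    }
    nn <- FNN::get.knnx(pred_pos[cl_cells, , drop = FALSE],
                        pred_pos[cl_genes, , drop = FALSE], k = k_eff)$nn.index
    xy <- t(apply(nn, 1, function(ix) {
      colMeans(resp_pos[cl_cells[ix], , drop = FALSE])
    }))
    tibble(node_id = cl_genes, node_type = "gene",
           x = unname(xy[, 1]), y = unname(xy[, 2]), cluster = cl)
  })
  dplyr::bind_rows(out)
}

#' UMAP embedding of cells
#'
#' Seeded library UMAP of the PC scores, returned in the package's
#' embedding-table form, for use as the external space of
#' [project_genes_external()].
#'
#' @param pca A `stardust_pca` (or numeric score matrix).
#' @param seed Integer seed (single-threaded optimization keeps the result
#'   reproducible).
#' @param n_neighbors UMAP neighborhood size (default 15).
#' @return Embedding tibble: `node_id`, `node_type` (`"cell"`), `x`, `y`.
#' @export
embed_umap <- function(pca, seed = 1, n_neighbors = 15) {
  scores <- if (inherits(pca, "stardust_pca")) pca$scores else as.matrix(pca)
  coords <- with_seed(seed, uwot::umap(scores, n_neighbors = n_neighbors,
                                       n_threads = 1, n_sgd_threads = 1,
                                       batch = TRUE))
  tibble(node_id = rownames(scores), node_type = "cell",
         x = coords[, 1], y = coords[, 2])
}
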