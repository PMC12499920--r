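toy_norm <- function(values) {
  structure(list(values = methods::as(Matrix::Matrix(values, sparse = TRUE),
                                      "generalMatrix"),
                 median_total = 1),
            class = "stardust_norm")
}

test_that("PCA reconstructs the centered matrix and clamps components", {
  set.seed(1)
  m <- matrix(rnorm(30 * 8), 30, 8)
  dimnames(m) <- list(paste0("c", 1:30), paste0("g", 1:8))
  expect_message(pca <- compute_pca(toy_norm(m), n_comp = 500), "clamped")
  expect_identical(pca$n_comp, 8L)
  recon <- pca$scores %*% t(pca$loadings)
  expect_equal(recon, sweep(m, 2, colMeans(m)), ignore_attr = TRUE)
  expect_equal(unname(sqrt(colSums(pca$loadings^2))), rep(1, pca$n_comp))
})

test_that("rank-1 data puts all variance on the first component", {
  t_vals <- seq(0, 1, length.out = 20)
  m <- outer(t_vals, c(1, 2, -1, 0.5))
  dimnames(m) <- list(paste0("c", 1:20), paste0("g", 1:4))
  pca <- compute_pca(toy_norm(m), n_comp = 3)
  ev <- pca$explained_variance
  expect_gt(ev[1] / sum(ev), 1 - 1e-10)
  expect_error(compute_pca(toy_norm(m * 0), n_comp = 2), "degenerate")
})

test_that("PCA-loading gene selection matches the brute-force ranking", {
  loadings <- rbind(gA = c(0.9, 0.1), gB = c(0.2, -0.95), gC = c(0.5, 0.5),
                    gD = c(0, 0), gE = c(-0.7, 0.2))
  pca <- structure(list(scores = matrix(0, 2, 2), loadings = loadings,
                        center = c(0, 0), explained_variance = c(1, 1),
                        n_comp = 2L), class = "stardust_pca")
  sel <- pca_gene_selection(pca, 5)
  brute <- names(sort(apply(abs(loadings), 1, max), decreasing = TRUE))
  expect_identical(sel$gene_id, brute)
  expect_identical(sel$gene_id[5], "gD")          # zero loadings rank last
  expect_setequal(pca_gene_selection(pca, 5)$gene_id, rownames(loadings))
})

test_that("cell edges follow exact kNN geometry and the union bound", {
  pts <- cbind(c(0, 1, 2), c(0, 0, 0))
  rownames(pts) <- c("a", "b", "c")
  e <- build_cell_edges(pts, k = 1)
  # middle point is the nearest neighbor of both ends
  expect_true(all(c("b") %in% c(e$from, e$to)))
  expect_true(nrow(e) <= 3 * 1)
  expect_true(all(e$class == "cell-cell"))
  expect_error(build_cell_edges(pts, k = 3), "smaller")

  set.seed(3)
  pts2 <- matrix(rnorm(50 * 5), 50, 5)
  rownames(pts2) <- paste0("c", 1:50)
  e2 <- build_cell_edges(pts2, k = 5)
  expect_lte(nrow(e2), 50 * 5)
})

test_that("approximate neighbor search overlaps the exact kNN graph", {
  set.seed(4)
  pts <- matrix(rnorm(50 * 5), 50, 5)
  rownames(pts) <- paste0("c", 1:50)
  exact <- build_cell_edges(pts, k = 5, exact = TRUE)
  approx <- build_cell_edges(pts, k = 5, exact = FALSE, seed = 2)
  key <- function(e) paste(e$from, e$to)
  overlap <- length(intersect(key(exact), key(approx))) / nrow(exact)
  expect_gte(overlap, 0.9)
})

test_that("cell edges are invariant under cell permutation", {
  set.seed(5)
  pts <- matrix(rnorm(30 * 4), 30, 4)
  rownames(pts) <- paste0("c", 1:30)
  e1 <- build_cell_edges(pts, k = 4)
  perm <- sample.int(30)
  e2 <- build_cell_edges(pts[perm, ], k = 4)
  key <- function(e) sort(paste(e$from, e$to))
  expect_identical(key(e1), key(e2))
})

test_that("each gene connects to its top-n cells by normalized expression", {
  vals <- rbind(c(5, 0, 1), c(4, 2, 0), c(1, 3, 0), c(0, 1, 0))
  dimnames(vals) <- list(paste0("c", 1:4), paste0("g", 1:3))
  norm <- toy_norm(vals)
  e <- build_gene_edges(norm, paste0("g", 1:3), n = 2)
  # brute-force top-2 per gene
  for (g in paste0("g", 1:3)) {
    brute <- rownames(vals)[head(order(-vals[, g], seq_len(4)), 2)]
    expect_setequal(e$from[e$to == g], brute)
  }
  # degree is exactly min(n, cells)
  e10 <- build_gene_edges(norm, paste0("g", 1:3), n = 10)
  expect_true(all(table(e10$to) == 4))
  # a gene expressed in one cell always includes that cell; ties resolve
  # deterministically in cell order
  e3 <- build_gene_edges(norm, "g3", n = 3)
  expect_true("c1" %in% e3$from)
  expect_identical(e3$from, c("c1", "c2", "c3"))
})

test_that("final-pass gene degrees follow the rank-decay rule", {
  # p = 5 - ceiling(i/10): 4 for ranks 1-10, 3 for ranks 11-20
  expect_identical(5L - as.integer(ceiling(c(1, 10, 11, 20) / 10)),
                   c(4L, 4L, 3L, 3L))
  set.seed(6)
  vals <- matrix(rpois(40 * 25, 3), 40, 25)
  dimnames(vals) <- list(paste0("c", 1:40), paste0("g", 1:25))
  norm <- toy_norm(vals)
  labels <- tibble::tibble(cell_id = rownames(vals),
                           cluster = rep(1:2, each = 20))
  markers <- tibble::tibble(cluster = rep(1:2, each = 10),
                            gene_id = paste0("g", 1:20),
                            rank_in_cluster = rep(c(1:5, 11:15), 2))
  e <- build_gene_edges_pass4(markers, labels, norm)
  deg <- table(e$to)
  for (r in seq_len(nrow(markers))) {
    expected_p <- 5 - ceiling(markers$rank_in_cluster[r] / 10)
    expect_identical(as.integer(deg[[markers$gene_id[r]]]), as.integer(expected_p))
    # edges go to cells of the gene's own cluster only
    own <- labels$cell_id[labels$cluster == markers$cluster[r]]
    expect_true(all(e$from[e$to == markers$gene_id[r]] %in% own))
  }
  # tiny cluster: connect to all its cells with a warning
  lab_small <- tibble::tibble(cell_id = rownames(vals)[1:22],
                              cluster = c(rep(1, 20), rep(2, 2)))
  mk_small <- tibble::tibble(cluster = 2, gene_id = "g1", rank_in_cluster = 1)
  expect_warning(e2 <- build_gene_edges_pass4(mk_small, lab_small, norm),
                 "fewer")
  expect_identical(nrow(e2), 2L)
})

test_that("the graph validator admits only the two legal edge classes", {
  cells <- c("c1", "c2"); genes <- c("g1", "g2")
  ok_cell <- tibble::tibble(from = "c1", to = "c2", class = "cell-cell")
  ok_gene <- tibble::tibble(from = "c1", to = "g1", class = "cell-gene")
  g <- cell_gene_graph(ok_cell, ok_gene, cells, genes)
  expect_s3_class(g, "stardust_graph")
  expect_true(all(g$edges$class %in% c("cell-cell", "cell-gene")))

  bad <- tibble::tibble(from = "g1", to = "g2", class = "cell-gene")
  expect_error(cell_gene_graph(ok_cell, bad, cells, genes), "gene-gene")
  loop <- tibble::tibble(from = "c1", to = "c1", class = "cell-cell")
  expect_error(cell_gene_graph(loop, ok_gene, cells, genes), "loop")
  dup <- dplyr::bind_rows(ok_gene, ok_gene)
  expect_error(cell_gene_graph(ok_cell, dup, cells, genes), "duplicate")
})

test_that("edge-list export round-trips bit-exactly", {
  sim <- small_sim()
  norm <- normalize_log(filter_genes(filter_cells(sim$counts[1:60, ])))
  pca <- compute_pca(norm, n_comp = 10)
  ce <- build_cell_edges(pca, k = 4)
  gs <- pca_gene_selection(pca, 20)
  ge <- build_gene_edges(norm, gs, n = 5)
  g <- cell_gene_graph(ce, ge, rownames(norm$values), unique(gs$gene_id))
  d <- withr::local_tempdir()
  f <- file.path(d, "graph.tsv")
  export_graph(g, f)
  back <- import_graph(f)
  expect_identical(back$edges, g$edges)
  expect_identical(back$nodes, g$nodes)
  # GraphML export is readable by igraph
  f2 <- file.path(d, "graph.graphml")
  export_graph(g, f2)
  ig <- igraph::read_graph(f2, format = "graphml")
  expect_equal(igraph::gorder(ig), nrow(g$nodes))
  expect_equal(igraph::gsize(ig), nrow(g$edges))
})
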