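two_group_norm <- function(g_vals, r_vals) {
  # one informative gene plus a filler gene so ranking has >= 2 genes
  vals <- cbind(gene_t = c(g_vals, r_vals),
                filler = rep(c(1, 1.01), length.out = length(g_vals) + length(r_vals)))
  rownames(vals) <- paste0("c", seq_len(nrow(vals)))
  structure(list(values = methods::as(Matrix::Matrix(vals, sparse = TRUE),
                                      "generalMatrix"),
                 median_total = 1), class = "stardust_norm")
}

test_that("overestimated-variance t statistic matches the hand oracle", {
  g <- c(1, 2, 3); r <- c(4, 5, 6, 7)
  norm <- two_group_norm(g, r)
  labels <- tibble::tibble(cell_id = rownames(norm$values),
                           cluster = rep(c(1L, 2L), c(3, 4)))
  mk <- rank_genes(norm, labels)
  row <- mk[mk$cluster == 1 & mk$gene_id == "gene_t", ]
  ora <- t_overestim_oracle(g, r)
  expect_equal(row$t_stat, ora$t, tolerance = 1e-12)
  expect_equal(row$pval, ora$p, tolerance = 1e-12)
  # antisymmetry under swapping group and rest
  row2 <- mk[mk$cluster == 2 & mk$gene_id == "gene_t", ]
  ora2 <- t_overestim_oracle(r, g)
  expect_equal(row2$t_stat, ora2$t, tolerance = 1e-12)
  expect_gt(row2$t_stat, 0)
  expect_lt(row$t_stat, 0)
})

test_that("identical group means give t = 0, p = 1; upregulation gives t > 0", {
  norm <- two_group_norm(c(1, 2, 3, 1, 2, 3), c(3, 2, 1, 3, 2, 1))
  labels <- tibble::tibble(cell_id = rownames(norm$values),
                           cluster = rep(c(1L, 2L), each = 6))
  mk <- rank_genes(norm, labels)
  row <- mk[mk$cluster == 1 & mk$gene_id == "gene_t", ]
  expect_equal(row$t_stat, 0)
  expect_equal(row$pval, 1)

  norm2 <- two_group_norm(c(2, 2, 2, 2), c(0, 0, 0, 0))
  labels2 <- tibble::tibble(cell_id = rownames(norm2$values),
                            cluster = rep(c(1L, 2L), each = 4))
  mk2 <- rank_genes(norm2, labels2)
  row2 <- mk2[mk2$cluster == 1 & mk2$gene_id == "gene_t", ]
  expect_gt(row2$t_stat, 0)
  expect_gt(row2$log2fc, 0)
})

test_that("BH adjustment and marker-table invariants hold on random data", {
  set.seed(13)
  vals <- matrix(rpois(60 * 30, 2) + rnorm(60 * 30, 0, 0.01), 60, 30)
  vals <- abs(vals)
  dimnames(vals) <- list(paste0("c", 1:60), paste0("g", 1:30))
  norm <- structure(list(values = methods::as(Matrix::Matrix(vals, sparse = TRUE),
                                              "generalMatrix"),
                         median_total = 1), class = "stardust_norm")
  labels <- tibble::tibble(cell_id = rownames(vals),
                           cluster = rep(1:3, each = 20))
  mk <- rank_genes(norm, labels)
  for (cl in 1:3) {
    sub <- mk[mk$cluster == cl, ]
    # BH within the cluster comparison equals the brute-force oracle
    expect_equal(sub$pval_adj, bh_oracle(sub$pval), tolerance = 1e-12)
    expect_true(all(sub$pval_adj >= sub$pval - 1e-15))
    # rank increases as t decreases
    expect_identical(sub$rank_in_cluster, seq_len(nrow(sub)))
    expect_true(all(diff(sub$t_stat) <= 0))
  }
})

test_that("clusters of size one are skipped, noise is excluded", {
  norm <- two_group_norm(c(1, 2, 3), c(4, 5, 6, 7))
  labels <- tibble::tibble(
    cell_id = rownames(norm$values),
    cluster = c(1L, 1L, 1L, 2L, 2L, 3L, -1L))
  expect_warning(mk <- rank_genes(norm, labels), "size 1")
  expect_setequal(unique(mk$cluster), c(1L, 2L))
})

test_that("pass-gene selection applies both strict filters and the fallback", {
  mk <- tibble::tibble(
    cluster = rep(1:2, each = 5),
    gene_id = c(paste0("a", 1:5), c("a1", paste0("b", 2:5))),
    rank_in_cluster = rep(1:5, 2),
    t_stat = c(10, 8, 6, 4, 2, 9, 7, 5, 3, 1),
    pval = rep(0.01, 10),
    pval_adj = c(0.01, 0.49, 0.5, 0.6, 0.01, 0.02, 0.3, 0.01, 0.49, 0.7),
    log2fc = c(2.0, 1.3, 2.0, 2.0, 1.2, 1.21, 2.5, 1.19, 1.3, 2.0))
  sel <- select_pass_genes(mk, p_adj_max = 0.5, lfc_min = 1.2, cap = 500)
  # hand evaluation: pval_adj < 0.5 AND log2fc > 1.2, log2fc = 1.2 excluded
  expect_setequal(sel$gene_id, c("a1", "a2", "b2", "b4"))
  # dedup keeps a1's best t (10, from cluster 1)
  expect_equal(sel$score[sel$gene_id == "a1"], 10)
  # cap truncates by t: survivors ranked a1 (t=10), a2 (8), b2 (7), b4 (3)
  sel2 <- select_pass_genes(mk, cap = 2)
  expect_identical(sel2$gene_id, c("a1", "a2"))
  # fallback on empty survivors
  fb <- tibble::tibble(gene_id = "z", method = "pca_loading", score = 1)
  expect_warning(out <- select_pass_genes(mk, p_adj_max = 1e-9, fallback = fb),
                 "falling back")
  expect_identical(out$gene_id, "z")
})

test_that("top markers are contiguous, upregulated, and capture planted genes", {
  mk <- tibble::tibble(
    cluster = rep(1L, 8), gene_id = paste0("g", 1:8),
    rank_in_cluster = 1:8, t_stat = 8:1, pval = 0.01, pval_adj = 0.02,
    log2fc = c(3, 2, -1, 1, 0.5, -2, 0.2, 0.1))
  # only 6 upregulated genes exist; per_cluster = 20 returns those 6
  top <- top_markers(rbind(mk, within(mk, cluster <- 2L)), per_cluster = 20)
  expect_identical(nrow(top[top$cluster == 1, ]), 6L)
  expect_identical(top$rank_in_cluster[top$cluster == 1], 1:6)
  expect_true(all(top$log2fc > 0))

  # planted markers occupy the top ranks on the synthetic fixture
  fit <- small_fit()
  sim <- small_sim()
  top5 <- fit$top_markers[fit$top_markers$rank_in_cluster <= 5, ]
  planted <- unlist(sim$truth$marker_map)
  expect_gte(mean(top5$gene_id %in% planted), 0.9)
})
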