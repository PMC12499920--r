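blobs <- function(n_per, centers, sd, seed = 1) {
  withr::with_seed(seed, {
    pos <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
      cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))
    }))
    tibble::tibble(node_id = paste0("c", seq_len(nrow(pos))),
                   node_type = "cell", x = pos[, 1], y = pos[, 2])
  })
}

test_that("DBSCAN resolves two distant blobs with no noise", {
  emb <- blobs(50, rbind(c(0, 0), c(100, 0)), sd = 1, seed = 2)
  lab <- dbscan_embed(emb, eps = 5, min_samples = 5)
  expect_identical(sort(unique(lab$cluster)), c(1L, 2L))
  expect_identical(sum(lab$cluster == -1L), 0L)
  # blob membership matches the split
  expect_identical(length(unique(lab$cluster[1:50])), 1L)
  expect_identical(length(unique(lab$cluster[51:100])), 1L)
})

test_that("DBSCAN degenerate geometries behave as documented", {
  # all points identical: one cluster
  emb <- tibble::tibble(node_id = paste0("c", 1:30), node_type = "cell",
                        x = 1, y = 2)
  lab <- dbscan_embed(emb, eps = 0.5, min_samples = 5)
  expect_identical(unique(lab$cluster), 1L)
  # a far-away isolated point is noise
  emb2 <- dplyr::bind_rows(blobs(30, rbind(c(0, 0)), sd = 1, seed = 3),
                           tibble::tibble(node_id = "lonely",
                                          node_type = "cell",
                                          x = 1000, y = 1000))
  lab2 <- dbscan_embed(emb2, eps = 5, min_samples = 5)
  expect_identical(lab2$cluster[lab2$cell_id == "lonely"], -1L)
  expect_error(dbscan_embed(emb, eps = -1, min_samples = 5), "positive")
})

test_that("DBSCAN agrees with the brute-force density-reachability oracle", {
  for (s in 1:4) {
    emb <- withr::with_seed(s, tibble::tibble(
      node_id = paste0("c", 1:120), node_type = "cell",
      x = c(rnorm(40), rnorm(40, 6), rnorm(40, 12)),
      y = c(rnorm(40), rnorm(40, 5), rnorm(40, -4))))
    eps <- 1.2; min_pts <- 5
    lab <- dbscan_embed(emb, eps = eps, min_samples = min_pts)$cluster
    ora <- dbscan_oracle(as.matrix(emb[, c("x", "y")]), eps, min_pts)
    # identical partition of core points (labels up to renaming)
    expect_equal(ari(lab[ora$core], ora$labels[ora$core]), 1)
    # identical noise set among non-core points with no core neighbor
    expect_identical(lab == -1L,
                     ora$labels == -1L &
                       vapply(ora$border_choices, length, integer(1)) == 0)
    # border points sit in a cluster that owns one of their core neighbors
    for (i in seq_along(lab)) {
      ch <- ora$border_choices[[i]]
      if (length(ch)) {
        mapped <- unique(ora$labels[ora$core & lab == lab[i]])
        expect_true(any(ch %in% mapped))
      }
    }
  }
})

test_that("post-hoc assignment follows majority vote and neighbor-mean coordinates", {
  set.seed(9)
  # sampled cells: two tight groups in PC space with known layout coords
  scores <- rbind(matrix(rnorm(40, 0, 0.1), 20, 2),
                  matrix(rnorm(40, 5, 0.1), 20, 2))
  rownames(scores) <- paste0("s", 1:40)
  emb <- tibble::tibble(node_id = rownames(scores), node_type = "cell",
                        x = c(rnorm(20, -10, 0.1), rnorm(20, 10, 0.1)),
                        y = 0)
  labels <- tibble::tibble(cell_id = rownames(scores),
                           cluster = rep(c(1L, 2L), each = 20),
                           source = "dbscan")
  # unanimous: a leftover near group 1 gets cluster 1 and the centroid of
  # its 20 same-cluster neighbors
  lo <- matrix(c(0.05, 0.05), 1, 2)
  rownames(lo) <- "left1"
  all_scores <- rbind(scores, lo)
  out <- posthoc_assign("left1", all_scores, labels, emb, k = 20)
  expect_identical(out$cluster, 1L)
  expect_equal(out$x, mean(emb$x[1:20]))
  # coordinates inside the bounding box of same-cluster neighbors
  expect_gte(out$x, min(emb$x[1:20])); expect_lte(out$x, max(emb$x[1:20]))

  # majority 11/9 goes to the majority cluster
  nn_lab <- tibble::tibble(cell_id = rownames(scores)[c(1:11, 21:29)],
                           cluster = rep(c(1L, 2L), c(11, 9)),
                           source = "dbscan")
  out2 <- posthoc_assign("left1", all_scores, nn_lab, emb, k = 20)
  expect_identical(out2$cluster, 1L)

  # k larger than the sampled count is clamped with a warning
  expect_warning(
    posthoc_assign("left1", all_scores, labels[1:5, ], emb, k = 20),
    "clamped")

  # labels never invented: outputs are a subset of sampled labels
  expect_true(all(out$cluster %in% labels$cluster))
  expect_error(posthoc_assign("s1", all_scores, labels, emb, k = 3),
               "overlap")
})

test_that("with subsampling disabled post-hoc is a no-op in the pipeline", {
  fit <- small_fit()
  expect_true(all(fit$labels$source == "dbscan"))
  expect_setequal(fit$labels$cell_id, fit$cell_coords$node_id)
})
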