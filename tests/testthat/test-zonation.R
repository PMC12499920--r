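test_that("Stouffer combination matches its closed forms", {
  coords <- cbind(x = 1:4, y = 0)
  rownames(coords) <- paste0("b", 1:4)
  z_row <- c(1, -1, 0.5, 2)
  raw <- z_row * 2 + 5   # standardizes back to z_row up to sd scaling
  scores <- rbind(g1 = raw, g2 = raw, g3 = raw, g4 = raw)
  colnames(scores) <- rownames(coords)
  bm <- binmap(scores, coords)
  zs <- t(scale(t(scores)))[1, ]
  # G identical rows combine to sqrt(G) * z
  expect_equal(unname(stouffer_scores(bm, paste0("g", 1:4))),
               unname(sqrt(4) * zs))
  # a single gene is its own z-vector
  expect_equal(unname(stouffer_scores(bm, "g1")), unname(zs))
})

test_that("Stouffer combination matches hand computation and is symmetric", {
  coords <- cbind(x = 1:4, y = 0); rownames(coords) <- paste0("b", 1:4)
  scores <- rbind(g1 = c(0.1, 0.9, 0.3, 0.5),
                  g2 = c(2, 4, 8, 1),
                  g3 = c(0, 0.2, 0.1, 0.9))
  colnames(scores) <- rownames(coords)
  bm <- binmap(scores, coords)
  hand <- colSums(t(apply(scores, 1, function(r) (r - mean(r)) / sd(r)))) / sqrt(3)
  expect_equal(unname(stouffer_scores(bm, c("g1", "g2", "g3"))), unname(hand))
  # symmetric in gene order
  expect_equal(stouffer_scores(bm, c("g3", "g1", "g2")),
               stouffer_scores(bm, c("g1", "g2", "g3")))
  # constant rows are dropped with a warning
  scores2 <- rbind(scores, g4 = rep(1, 4))
  bm2 <- binmap(scores2, coords)
  expect_warning(out <- stouffer_scores(bm2, paste0("g", 1:4)), "constant")
  expect_equal(out, stouffer_scores(bm, paste0("g", 1:3)))
})

test_that("binarization thresholds behave at the extremes and the median", {
  s <- c(b1 = 0.1, b2 = 0.4, b3 = 0.6, b4 = 0.9)
  expect_true(all(binarize_scores(s, min(s) - 1)))
  expect_false(any(binarize_scores(s, max(s) + 1)))
  expect_identical(sum(binarize_scores(s, median(s))), 2L)
})

test_that("cluster correspondence reproduces Pearson correlation", {
  a <- rbind(cl1 = c(1, 2, 3, 4, 5), cl2 = c(5, 3, 1, 2, 2))
  colnames(a) <- paste0("g", 1:5)
  self <- cluster_correspondence(a, a)
  expect_equal(unname(diag(self)), c(1, 1))
  neg <- cluster_correspondence(a, rbind(cl1 = -a[1, ]))
  expect_equal(neg["cl1", "cl1"], -1)
  # hand formula on two 5-gene vectors
  x <- a[1, ]; y <- a[2, ]
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(self["cl1", "cl2"], hand)
  # zero-variance vectors yield missing entries
  flat <- rbind(cl1 = rep(2, 5)); colnames(flat) <- paste0("g", 1:5)
  expect_true(is.na(cluster_correspondence(flat, a)[1, 1]))
})

test_that("tree regression nails a linear signal and returns to null on noise", {
  set.seed(2)
  n_bins <- 200
  coords <- cbind(x = runif(n_bins, -2, 2), y = runif(n_bins, -1, 1))
  rownames(coords) <- paste0("b", seq_len(n_bins))
  scores <- rbind(g1 = coords[, 1], g2 = 2 * coords[, 1] + 1,
                  g3 = 3 * coords[, 2], g4 = coords[, 2] - 1)
  colnames(scores) <- rownames(coords)
  bm <- binmap(scores, coords)
  res <- predict_coordinates_rmse(bm, paste0("g", 1:4), n_boot = 50, seed = 1)
  expect_identical(nrow(res), 50L * 2L)
  expect_true(all(res$rmse >= 0))
  ratio <- tapply(res$rmse, res$coord, mean) / tapply(res$rmse_null, res$coord, mean)
  expect_true(all(ratio <= 0.1))

  # pure-noise predictors: never better than the null model, and with the
  # pruned (default-control) tree the error sits at the null level; the
  # fully deep tree overfits noise and exceeds it
  scores_n <- matrix(rnorm(4 * n_bins), 4, n_bins,
                     dimnames = list(paste0("g", 1:4), rownames(coords)))
  bmn <- binmap(scores_n, coords)
  resn <- predict_coordinates_rmse(bmn, paste0("g", 1:4), n_boot = 20, seed = 1)
  expect_gt(mean(resn$rmse) / mean(resn$rmse_null), 0.95)
  resp <- predict_coordinates_rmse(bmn, paste0("g", 1:4), n_boot = 20, seed = 1,
                                   control = rpart::rpart.control(xval = 0))
  rn <- mean(resp$rmse) / mean(resp$rmse_null)
  expect_lt(abs(rn - 1), 0.2)
})

test_that("synthetic bin-map zonation masks overlap the true arcs", {
  sb <- simulate_binmap(n_bins = 300, n_clusters = 5, genes_per_cluster = 20,
                        noise_sd = 0.1, seed = 3)
  mk <- tibble::tibble(
    cluster = rep(1:5, each = 20),
    gene_id = unlist(sb$truth$marker_map),
    rank_in_cluster = rep(1:20, 5))
  zs <- zonation_scores(sb$binmap, mk, expected_fraction = 1 / 5)
  for (cl in 1:5) {
    sel <- zs$selected[zs$cluster == cl]
    truth <- sb$truth$arc_masks[zs$bin_id[zs$cluster == cl], as.character(cl)]
    jac <- sum(sel & truth) / sum(sel | truth)
    expect_gte(jac, 0.7)
  }
})
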