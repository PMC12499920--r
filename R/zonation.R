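# Spatial zonation of cell-type clusters: where on a reference bin map
# (e.g. a virtual embryo) does a cluster's marker-gene signal concentrate.

#' Stouffer combination of gene mapping scores per bin
#'
#' Each gene's mapping-score vector is standardized across bins to
#' z-scores, and the z-scores are combined per bin as `sum(z) / sqrt(G)`
#' (Stouffer's method). Genes with zero variance across bins carry no
#' positional information and are dropped with a warning.
#'
#' @param binmap A `stardust_binmap`.
#' @param genes Character vector of gene ids (e.g. a cluster's top
#'   markers); must be present in the bin map.
#' @return Named numeric vector of combined z-scores, one per bin.
#' @export
stouffer_scores <- function(binmap, genes) {
  if (length(genes) < 1) abort("`genes` must contain at least one gene.")
  missing <- setdiff(genes, rownames(binmap$scores))
  if (length(missing)) {
    abort(paste0("genes absent from the bin map: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  m <- binmap$scores[genes, , drop = FALSE]
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    warn(paste0("constant score rows dropped: ",
                paste(genes[sds == 0], collapse = ", ")))
    m <- m[sds > 0, , drop = FALSE]
    if (nrow(m) == 0) abort("all score rows were constant.")
  }
  z <- t(scale(t(m)))
  colSums(z) / sqrt(nrow(z))
}

#' Binarize per-bin scores at a threshold
#'
#' @param scores Numeric per-bin scores.
#' @param threshold Bins with `score > threshold` become `TRUE`.
#' @return Logical vector, same names as `scores`.
#' @export
binarize_scores <- function(scores, threshold) {
  if (any(!is.finite(scores))) abort("`scores` must be finite.")
  scores > threshold
}

#' Cluster correspondence across two assays
#'
#' Pearson correlation between cluster-wise average expression vectors of
#' a shared gene panel, for every pair of clusters across two datasets
#' (e.g. scRNA-seq clusters vs in-situ positional-bin clusters).
#'
#' @param meansA,meansB Numeric clusters-by-genes matrices over the same
#'   gene panel (columns matched by name when named).
#' @return Matrix of Pearson r, rows = clusters of A, columns = clusters
#'   of B; entries are `NA` where a mean vector has zero variance.
#' @export
cluster_correspondence <- function(meansA, meansB) {
  meansA <- as.matrix(meansA); meansB <- as.matrix(meansB)
  if (!is.null(colnames(meansA)) && !is.null(colnames(meansB))) {
    shared <- intersect(colnames(meansA), colnames(meansB))
    if (length(shared) < 2) abort("fewer than 2 shared genes between the panels.")
    meansA <- meansA[, shared, drop = FALSE]
    meansB <- meansB[, shared, drop = FALSE]
  } else if (ncol(meansA) != ncol(meansB)) {
    abort("gene panels differ in size and are unnamed.")
  }
  out <- matrix(NA_real_, nrow(meansA), nrow(meansB),
                dimnames = list(rownames(meansA), rownames(meansB)))
  for (i in seq_len(nrow(meansA))) {
    for (j in seq_len(nrow(meansB))) {
      a <- meansA[i, ]; b <- meansB[j, ]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) next
      out[i, j] <- cor(a, b)
    }
  }
  out
}

#' Bootstrapped spatial-coordinate prediction error
#'
#' How well do marker-gene mapping scores predict bin positions? For each
#' of `n_boot` bootstrap replicates, bins are sampled with replacement as
#' the training set and the out-of-bag bins form the validation set; a
#' decision-tree regressor (one per coordinate, gene scores as predictors)
#' is fit and its validation RMSE recorded, alongside the null RMSE of
#' predicting the training mean. Replicates with an empty out-of-bag set
#' are resampled (logged).
#'
#' @param binmap A `stardust_binmap`.
#' @param feature_genes Gene ids used as predictors (the paper-style design
#'   uses ~100 DE genes, an equal number per cluster).
#' @param n_boot Number of bootstrap replicates (default 50).
#' @param seed Integer seed.
#' @param control `rpart` control; the default grows deep trees
#'   (`minsplit = 2`, `minbucket = 1`, `cp = 0`).
#' @return Tibble with one row per replicate and coordinate: `replicate`,
#'   `coord`, `rmse`, `rmse_null`.
#' @export
predict_coordinates_rmse <- function(binmap, feature_genes, n_boot = 50,
                                     seed = 1,
                                     control = rpart::rpart.control(
                                       minsplit = 2, minbucket = 1, cp = 0,
                                       maxdepth = 30, xval = 0)) {
  missing <- setdiff(feature_genes, rownames(binmap$scores))
  if (length(missing)) {
    abort(paste0("feature genes absent from the bin map: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  x <- t(binmap$scores[feature_genes, , drop = FALSE])
  colnames(x) <- make.names(colnames(x))
  coords <- binmap$coords
  cn <- colnames(coords) %||% paste0("coord", seq_len(ncol(coords)))
  n <- nrow(x)
  with_seed(seed, {
    rows <- list()
    for (b in seq_len(n_boot)) {
      repeat {
        train <- sample.int(n, n, replace = TRUE)
        oob <- setdiff(seq_len(n), unique(train))
        if (length(oob) > 0) break
        inform("empty out-of-bag set; replicate resampled.")
      }
      for (ci in seq_len(ncol(coords))) {
        df_tr <- data.frame(y = coords[train, ci], x[train, , drop = FALSE])
        fit <- rpart::rpart(y ~ ., data = df_tr, method = "anova",
                            control = control)
        pred <- predict(fit, data.frame(x[oob, , drop = FALSE]))
        truth <- coords[oob, ci]
        rows[[length(rows) + 1L]] <- tibble(
          replicate = b, coord = cn[ci],
          rmse = sqrt(mean((pred - truth)^2)),
          rmse_null = sqrt(mean((mean(coords[train, ci]) - truth)^2))
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Per-cluster zonation scores on a bin map
#'
#' Convenience wrapper: combines each cluster's top markers with
#' [stouffer_scores()] and optionally binarizes at a quantile-calibrated
#' threshold (chosen so the selected bin count matches
#' `expected_fraction` of the bins).
#'
#' @param binmap A `stardust_binmap`.
#' @param markers A marker tibble ([top_markers()] output); only genes
#'   present in the bin map are used.
#' @param expected_fraction If non-`NULL`, also return binarized masks
#'   thresholded at the `1 - expected_fraction` score quantile.
#' @return Tibble: `cluster`, `bin_id`, `score`, and `selected` when
#'   binarized.
#' @export
zonation_scores <- function(binmap, markers, expected_fraction = NULL) {
  out <- lapply(sort(unique(markers$cluster)), function(cl) {
    genes <- markers$gene_id[markers$cluster == cl]
    genes <- intersect(genes, rownames(binmap$scores))
    if (length(genes) == 0) return(NULL)
    s <- stouffer_scores(binmap, genes)
    res <- tibble(cluster = cl, bin_id = names(s), score = unname(s))
    if (!is.null(expected_fraction)) {
      thr <- quantile(s, probs = 1 - expected_fraction)
      res$selected <- binarize_scores(s, thr)
    }
    res
  })
  dplyr::bind_rows(out)
}
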