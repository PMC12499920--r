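#' Filter low-complexity cells
#'
#' Removes cells that express fewer than 30% of the average number of
#' expressed genes across all input cells, where a gene counts as expressed
#' in a cell when its count is positive. The threshold is computed once on
#' the input, so the filter is idempotent.
#'
#' @param counts Cells-by-genes count matrix (dense or sparse) with cell and
#'   gene ids as dimnames.
#' @param min_fraction Fraction of the mean expressed-gene count below which
#'   a cell is removed (default 0.3).
#' @return The count matrix restricted to retained cells; gene set unchanged.
#' @export
filter_cells <- function(counts, min_fraction = 0.3) {
  counts <- as_count_matrix(counts)
  if (nrow(counts) == 0) abort("`counts` has no cells.")
  validate_counts(counts)
  ng <- n_expressed_genes(counts)
  keep <- ng >= min_fraction * mean(ng)
  if (!any(keep)) abort("empty after filtering: all cells fell below the expressed-gene threshold.")
  counts[keep, , drop = FALSE]
}

#' Filter rarely detected genes
#'
#' Retains genes detected (count > 0) in at least `min_cells` cells.
#'
#' @inheritParams filter_cells
#' @param min_cells Minimum number of cells a gene must be detected in
#'   (default 3).
#' @return The count matrix restricted to retained genes; cell set unchanged.
#' @export
filter_genes <- function(counts, min_cells = 3) {
  counts <- as_count_matrix(counts)
  if (nrow(counts) == 0) abort("`counts` has no cells.")
  validate_counts(counts)
  keep <- Matrix::colSums(counts > 0) >= min_cells
  counts[, keep, drop = FALSE]
}

#' Median-scale and log-transform counts
#'
#' Scales each cell's counts so its total equals the median of the
#' pre-normalization per-cell totals, then applies `log1p` (natural log of
#' one plus the scaled value).
#'
#' @inheritParams filter_cells
#' @return A `stardust_norm` object: list with `values` (sparse
#'   cells-by-genes matrix of log1p median-scaled counts) and `median_total`
#'   (the scaling target).
#' @export
normalize_log <- function(counts) {
  counts <- validate_counts(as_count_matrix(counts))
  totals <- Matrix::rowSums(counts)
  if (any(totals == 0)) {
    bad <- rownames(counts)[totals == 0]
    abort(paste0("cells with zero total count cannot be normalized: ",
                 paste(head(bad, 5), collapse = ", "),
                 if (length(bad) > 5) ", ..." else ""))
  }
  median_total <- median(totals)
  scaled <- Matrix::Diagonal(x = median_total / totals) %*% counts
  values <- scaled
  values@x <- log1p(values@x)
  values <- as(as(values, "CsparseMatrix"), "generalMatrix")
  dimnames(values) <- dimnames(counts)
  structure(list(values = values, median_total = median_total),
            class = "stardust_norm")
}

#' @export
print.stardust_norm <- function(x, ...) {
  cat("<stardust_norm> ", nrow(x$values), " cells x ", ncol(x$values),
      " genes, median total ", format(x$median_total), "\n", sep = "")
  invisible(x)
}

norm_values <- function(norm) {
  if (inherits(norm, "stardust_norm")) norm$values else norm
}

#' Select highly variable genes (normalized dispersion)
#'
#' Ranks genes by normalized dispersion computed on the expm1 of the
#' normalized log expression (i.e. on median-scaled counts): per gene,
#' dispersion = variance/mean; genes are binned into 20 equal-frequency
#' bins by mean expression and the dispersion is robustly z-scored within
#' each bin (median/MAD). The top `n_top` genes by normalized dispersion
#' are returned.
#'
#' @param norm A `stardust_norm` object from [normalize_log()].
#' @param n_top Number of genes to select (default 500).
#' @param n_bins Number of mean-expression bins for the z-scoring
#'   (default 20).
#' @return A gene-selection tibble: `gene_id`, `method`
#'   (`"hvg_dispersion"`), `score`, ordered by decreasing score.
#' @export
select_hvgs <- function(norm, n_top = 500, n_bins = 20) {
  values <- norm_values(norm)
  n_genes <- ncol(values)
  if (n_top > n_genes) {
    abort(paste0("n_top (", n_top, ") exceeds the number of genes (", n_genes, ")."))
  }
  # moments of expm1(values) without densifying
  ex <- values
  ex@x <- expm1(ex@x)
  mu <- Matrix::colMeans(ex)
  ex2 <- ex
  ex2@x <- ex2@x^2
  m2 <- Matrix::colMeans(ex2)
  n <- nrow(values)
  v <- (m2 - mu^2) * n / max(1, n - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  # equal-frequency bins on the mean
  n_bins <- max(1L, min(n_bins, n_genes))
  br <- unique(quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(mu, breaks = br, include.lowest = TRUE, labels = FALSE)
  z <- disp
  for (b in unique(bin)) {
    idx <- which(bin == b)
    med <- median(disp[idx])
    md <- median(abs(disp[idx] - med))
    if (md == 0) md <- 1
    z[idx] <- (disp[idx] - med) / md
  }
  ord <- order(-z, colnames(values), method = "radix")
  sel <- head(ord, n_top)
  tibble(gene_id = colnames(values)[sel], method = "hvg_dispersion",
         score = z[sel])
}
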