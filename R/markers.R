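#' One-vs-rest marker ranking with the overestimated-variance t-test
#'
#' For each cluster g against the rest r, the statistic is
#' `t = (mu_g - mu_r) / sqrt(s_g^2/n_g + s_r^2/n_g)`: the
#' overestimated-variance variant divides *both* variance terms by the
#' focal group's size `n_g`, inflating the standard error conservatively.
#' Degrees of freedom follow Welch-Satterthwaite on those same two terms;
#' p-values are two-sided and Benjamini-Hochberg adjusted across genes
#' within each cluster comparison. The log2 fold change is computed on
#' expm1-back-transformed means of the log values with a 1e-9 epsilon.
#' Noise cells (cluster -1) are excluded entirely; clusters of size 1 are
#' skipped with a warning.
#'
#' @param norm A `stardust_norm` object.
#' @param labels Cluster-assignment tibble (`cell_id`, `cluster`).
#' @param var_floor Lower bound on variances (default 1e-9) so constant
#'   genes do not divide by zero.
#' @return A marker tibble: `cluster`, `gene_id`, `rank_in_cluster`
#'   (1-based, by decreasing t), `t_stat`, `pval`, `pval_adj`, `log2fc`.
#' @export
rank_genes <- function(norm, labels, var_floor = 1e-9) {
  values <- norm_values(norm)
  labels <- labels[labels$cluster != -1, ]
  labels <- labels[labels$cell_id %in% rownames(values), ]
  sizes <- table(labels$cluster)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warn(paste0("clusters of size 1 skipped: ", paste(small, collapse = ", ")))
    labels <- labels[!labels$cluster %in% as.integer(small), ]
    sizes <- table(labels$cluster)
  }
  if (length(sizes) < 2) abort("marker ranking needs at least 2 clusters with >= 2 cells.")
  mom <- function(cells) {
    m <- values[cells, , drop = FALSE]
    n <- length(cells)
    mu <- Matrix::colMeans(m)
    m2 <- m; m2@x <- m2@x^2
    v <- (Matrix::colMeans(m2) - mu^2) * n / (n - 1)
    list(n = n, mu = mu, v = pmax(v, 0))
  }
  out <- lapply(sort(as.integer(names(sizes))), function(cl) {
    g_cells <- labels$cell_id[labels$cluster == cl]
    r_cells <- labels$cell_id[labels$cluster != cl]
    g <- mom(g_cells); r <- mom(r_cells)
    vg <- pmax(g$v, var_floor); vr <- pmax(r$v, var_floor)
    # both variance terms divided by the focal group size
    term_g <- vg / g$n
    term_r <- vr / g$n
    se <- sqrt(term_g + term_r)
    t <- (g$mu - r$mu) / se
    df <- (term_g + term_r)^2 /
      (term_g^2 / (g$n - 1) + term_r^2 / (r$n - 1))
    p <- 2 * pt(-abs(t), df)
    padj <- p.adjust(p, method = "BH")
    lfc <- log2((expm1(g$mu) + 1e-9) / (expm1(r$mu) + 1e-9))
    ord <- order(-t, colnames(values), method = "radix")
    tibble(cluster = cl, gene_id = colnames(values)[ord],
           rank_in_cluster = seq_along(ord),
           t_stat = unname(t[ord]), pval = unname(p[ord]),
           pval_adj = unname(padj[ord]), log2fc = unname(lfc[ord]))
  })
  dplyr::bind_rows(out)
}

#' Select genes for the next network-building pass
#'
#' Takes the union over clusters of genes with `pval_adj < p_adj_max` and
#' `log2fc > lfc_min` (both strict), deduplicated keeping each gene's best
#' (largest) t statistic, truncated to the `cap` best by t. When nothing
#' passes, the supplied `fallback` selection is returned with a warning.
#'
#' @param markers A marker tibble from [rank_genes()].
#' @param p_adj_max Adjusted p-value cutoff, exclusive (default 0.5).
#' @param lfc_min log2 fold-change cutoff, exclusive (default 1.2).
#' @param cap Maximum number of genes returned (default 500).
#' @param fallback Optional gene-selection tibble used when no gene passes.
#' @return A gene-selection tibble: `gene_id`, `method` (`"de"`), `score`
#'   (the best t statistic), ordered by decreasing score.
#' @export
select_pass_genes <- function(markers, p_adj_max = 0.5, lfc_min = 1.2,
                              cap = 500, fallback = NULL) {
  if (nrow(markers) == 0) abort("`markers` is empty.")
  hits <- markers[markers$pval_adj < p_adj_max & markers$log2fc > lfc_min, ]
  if (nrow(hits) == 0) {
    if (!is.null(fallback)) {
      warn("no gene passed the DE filters; falling back to the PCA-loading selection.")
      return(fallback)
    }
    return(tibble(gene_id = character(), method = "de", score = numeric()))
  }
  hits <- hits[order(-hits$t_stat, hits$gene_id, method = "radix"), ]
  hits <- hits[!duplicated(hits$gene_id), ]
  hits <- head(hits, cap)
  tibble(gene_id = hits$gene_id, method = "de", score = hits$t_stat)
}

#' Top upregulated markers per cluster
#'
#' Per cluster, the `per_cluster` highest-ranked genes with positive log2
#' fold change; fewer are returned when a cluster lacks them. Ranks are
#' rewritten to be contiguous within each cluster.
#'
#' @param markers A marker tibble from [rank_genes()].
#' @param per_cluster Markers per cluster (default 20).
#' @return A marker tibble restricted to the top upregulated genes.
#' @export
top_markers <- function(markers, per_cluster = 20) {
  up <- markers[markers$log2fc > 0, ]
  up <- dplyr::group_by(up, .data$cluster)
  up <- dplyr::slice_min(up, .data$rank_in_cluster, n = per_cluster,
                         with_ties = FALSE)
  up <- dplyr::mutate(up, rank_in_cluster = dplyr::row_number(.data$rank_in_cluster))
  dplyr::ungroup(up)
}
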