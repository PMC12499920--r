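# stardust

Cells and their marker genes on one 2D map.

Standard single-cell RNA-seq workflows produce two disconnected artifacts:
a low-dimensional scatter of cells (UMAP/t-SNE) and a differential-expression
heatmap of marker genes. Cross-referencing the two is tedious, and the
embedding that looks continuous often contradicts the clustering that looks
discrete. `stardust` addresses both problems by embedding cells *and* genes
as nodes of one heterogeneous network and laying that network out with a
force-directed algorithm, so each cluster's markers end up inscribed inside
the cluster itself. It is aimed at analysts of scRNA-seq and spatial
transcriptomics data who want clustering, visualization, and marker placement
out of a single, resolution-free procedure.

## The method

A **cell-gene nearest-neighbor network** (CGNNN) has typed nodes (cell or
gene) and exactly two legal classes of unit-weight edges:

- *cell-cell*: each cell is connected to its *k* = 20 nearest cells by
  Euclidean distance in PCA space (approximate search above 2000 cells);
- *cell-gene*: each selected gene is connected to the *n* = 10 cells where
  its normalized expression is highest.

The network is laid out in 2D by simulated annealing (OpenOrd family) over
the objective

```
min_{x_1..x_N}  Σ_i ( Σ_j w_ij · d(x_i, x_j)²  +  D_{x_i} ),    w_ij = 1
```

where `d` is Euclidean distance and `D_{x_i}` the local node density near
`x_i`, with an edge-cutting heuristic controlling white space. DBSCAN on the
layout yields clusters; a one-vs-rest *overestimated-variance t-test*

```
t = (μ_g − μ_r) / sqrt(s_g²/n_g + s_r²/n_g)
```

(both variance terms divided by the focal group's size — a conservative
standard error) ranks genes per cluster; genes with adjusted *P* < .5 and
log2 fold change > 1.2 rewire the network. Four passes run in total:
pass 1 seeds the gene set from PCA loadings, passes 2-3 refine it with DE
genes, and pass 4 rebuilds the network from the top 20 markers per cluster
with rank-decayed connectivity (`p = 5 − ⌈i/10⌉` cells for the rank-*i*
marker) purely to place genes, which a per-cluster K-nearest-neighbor
regression (K = 5) then maps back into the pass-3 cell space — or onto any
external embedding such as UMAP.

Around the core sit: **structure-preserving subsampling** (per-cluster
sampling proportion `p = p_l − e^(−s/k)(p_l − p_u)`, so rare populations are
retained at a higher rate) with post-hoc majority-vote assignment of
held-out cells; **spatial zonation scoring** (Stouffer combination
`Σ z / √G` of marker-gene mapping scores across positional bins, with
binarization and cross-assay cluster correspondence by Pearson correlation);
bootstrapped **coordinate prediction** from marker genes with decision
trees; NMI/ARI/silhouette **evaluation metrics**; and a seeded
negative-binomial **count simulator** with planted clusters and markers.

## Worked example

```r
library(stardust)

sim <- simulate_counts(n_cells = 300, n_genes = 600, n_clusters = 5,
                       markers_per_cluster = 30, log2fc = 2,
                       nb_dispersion = 0.3, seed = 11)
fit <- run_stardust(sim$counts, stardust_config(seed = 11, sps = FALSE))
fit
#> <stardust_fit> 300 cells, 100 projected genes, 5 clusters
#> # A tibble: 4 × 4
#>    pass n_genes n_clusters ari_prev
#>   <int>   <int>      <int>    <dbl>
#> 1     1     500          5   NA
#> 2     2     150          5    0.979
#> 3     3     150          5    0.966
#> 4     4     100         NA   NA
```

The pass log reads: pass 1 built the network from 500 PCA-selected genes
and found 5 clusters; passes 2-3 rebuilt it from 150 DE genes each and the
clustering stayed essentially unchanged (ARI to the previous pass 0.97+);
pass 4 used the 100 top markers (20 per cluster) to place genes. Against
the planted truth:

```r
truth <- setNames(sim$truth$labels$cluster, sim$truth$labels$cell_id)
evaluate_clustering(fit$cell_coords, fit$labels, truth)
#> # A tibble: 1 × 4
#>   n_clusters silhouette   nmi   ari
#>        <int>      <dbl> <dbl> <dbl>
#> 1          5      0.881 0.973 0.979

head(fit$top_markers, 5)
#> # A tibble: 5 × 7
#>   cluster gene_id rank_in_cluster t_stat     pval pval_adj log2fc
#>     <int> <chr>             <int>  <dbl>    <dbl>    <dbl>  <dbl>
#> 1       1 gene16                1   11.9 4.78e-26 2.87e-23   2.38
#> 2       1 gene14                2   11.7 6.02e-25 1.81e-22   2.32
#> 3       1 gene9                 3   11.4 5.91e-23 1.18e-20   2.52
#> 4       1 gene20                4   11.2 1.63e-22 2.45e-20   2.48
#> 5       1 gene15                5   10.8 7.07e-22 8.48e-20   2.31
```

All five planted populations are recovered (ARI 0.98) and the top markers
are the planted marker genes (`gene1`-`gene150` carry the fold change).
`autoplot(fit)` draws the co-embedding with marker labels;
`tidy(fit)`/`glance(fit)` give per-node and one-row summaries;
`write_stardust(fit, dir)` writes `coordinates.csv`, `markers.csv` and a
run manifest. A shell front-end lives in `exec/stardust`
(`run` / `simulate` / `evaluate` subcommands).

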