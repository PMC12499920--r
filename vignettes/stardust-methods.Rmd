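---
title: "Methods: iterative cell-gene co-embedding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: iterative cell-gene co-embedding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(stardust)
```

## The model

`stardust` treats visualization and clustering as one problem. Cells and
genes are nodes of a single heterogeneous network with two legal edge
classes, both unit weight:

* **cell–cell** edges connect each cell to its $k$ nearest cells
  (Euclidean distance on principal-component scores of the log-normalized
  expression);
* **cell–gene** edges connect each selected gene to the $n$ cells in which
  its normalized expression is highest.

Gene–gene edges are illegal and rejected by a validator: genes interact
with the map only through the cells that express them. Laying this network
out in 2D with a force-directed algorithm makes expression-similar cells
coalesce and pulls each gene into the territory of its top-expressing
cells, so a cluster's markers are inscribed inside the cluster.

The layout minimizes, by simulated annealing,

$$\min_{x_1,\dots,x_N} \sum_i \Big( \sum_j w_{ij}\, d(x_i, x_j)^2 + D_{x_i} \Big),
\qquad w_{ij} = 1,$$

where $d$ is Euclidean distance and $D_{x_i}$ is the local density near
$x_i$. The attraction term contracts edges; the density term is the only
repulsive force and is what creates white space between communities.

### The four passes

The gene set used to wire the network is itself refined iteratively —
clustering and marker detection bootstrap each other, in the spirit of an
expectation–maximization loop:

1. **Pass 1** wires genes by PCA: the 500 genes with the largest absolute
   loading across the retained components.
2. **Passes 2–3** re-wire with differentially expressed genes: one-vs-rest
   tests against the current DBSCAN clusters, keeping genes with adjusted
   $P < 0.5$ and $\log_2$ fold change $> 1.2$ (both strict), capped at 500.
3. **Pass 4** keeps only the top 20 upregulated markers per cluster and
   connects the rank-$i$ marker to $p = 5 - \lceil i/10 \rceil$ cells of
   its own cluster (4 cells for ranks 1–10, 3 for ranks 11–20): better
   markers anchor to more cells.

Cell coordinates and cluster labels are taken from **pass 3**. Pass 4
exists only to place genes: a per-cluster K-nearest-neighbor regression is
fit from the cluster's cells (predictors: pass-4 coordinates; responses:
pass-3 coordinates, each dimension individually) and applied to the
cluster's genes. Because a KNN prediction is a mean of K training
responses, every projected gene lands inside the convex hull of its
cluster's cells — the co-location property the tests verify. The same
regression places genes onto any external embedding (e.g. `embed_umap()`);
we use pass-4 coordinates as predictors there too, a configurable choice —
pass-4 is the only space where genes have coordinates at all, so it is the
natural predictor space.

### Marker statistics

The per-cluster ranking uses the *overestimated-variance* one-vs-rest
$t$ statistic

$$t = \frac{\mu_g - \mu_r}{\sqrt{s_g^2/n_g + s_r^2/n_g}},$$

in which **both** variance terms are divided by the focal group's size
$n_g$. Compared to Welch's $t$, the rest-group term $s_r^2/n_g$ is much
larger than $s_r^2/n_r$ whenever the rest is the majority, so the standard
error is deliberately inflated and the test conservative — appropriate
when the "groups" were themselves estimated from the same data. Degrees of
freedom follow Welch–Satterthwaite on the two inflated terms; p-values are
two-sided and Benjamini–Hochberg adjusted across genes *within* each
cluster comparison (each cluster ranking is its own family). The
$\log_2$ fold change back-transforms the log-means
($\log_2\frac{e^{\mu_g}-1+\varepsilon}{e^{\mu_r}-1+\varepsilon}$,
$\varepsilon = 10^{-9}$).

The adjusted-$P$ cutoff of 0.5 deserves a note: it is permissive — a
conventional analysis would use 0.05 — but the filter's job here is gene
*selection for network wiring*, not discovery with error control, and a
permissive gate keeps the gene pool large on noisy data. Both the cutoff
and the fold-change threshold are config parameters
(`stardust_config(p_adj_max=, lfc_min=)`).

## Preprocessing

Cells expressing fewer than 30% of the mean number of expressed genes are
removed (threshold computed once on the input, making the filter
idempotent); genes detected in fewer than 3 cells are removed, in that
order. Counts are scaled per cell to the median pre-normalization total
and `log1p`-transformed. Highly-variable-gene selection (available as an
alternative seeding) computes dispersion = variance/mean on the
*back-transformed* (expm1) values and robustly z-scores it within 20
equal-frequency mean bins (median/MAD) — dispersion varies systematically
with the mean, and binning compares genes only to peers of similar
abundance.

## Structure-preserving subsampling

For large datasets the layout's node count is bounded by sampling each
preliminary cluster (modularity-based communities of the cell kNN graph)
at the proportion

$$p_i = p_l - e^{-s_i/k}\,(p_l - p_u),$$

which decays from $p_u$ for tiny clusters to $p_l$ for huge ones — rare
populations are kept nearly whole. The bounds and scale are not fixed by
the design, so the package chooses $p_l = 0.3$, $p_u = 0.9$, $k = 500$:
clusters of a few hundred cells or fewer retain most of their members
while the largest clusters shrink toward 30%. Per-cluster sample counts
round half-away-from-zero and are floored at 1, so no cluster disappears.
Subsampling is skipped entirely at or below 5000 cells (default): it
exists for scalability, and small data needs none. Held-out cells are
assigned *post hoc*: majority vote among their $k = 20$ nearest sampled
cells in PC space (ties broken by the single nearest neighbor), with
coordinates set to the mean of the same-cluster neighbors. PC space is
used for the query because held-out cells have no layout coordinates
before assignment.

## Clustering

DBSCAN runs on the 2D layout of the sampled cells. `min_samples` defaults
to 20, mirroring the neighbor parameter $k$. When `eps` is not given it is
set from the knee of the sorted `min_samples`-nearest-neighbor distance
curve (maximum distance to the chord between the curve's endpoints) — the
standard automatic calibration, and the right one here because layout
scale is an artifact of the annealing schedule, not of the data. Noise
cells keep the sentinel label -1, keep their coordinates, and are excluded
from marker computation (configurable in principle; excluded is the
default because DE against a "cluster" of stragglers is not meaningful).

## The annealer

The bespoke backend follows the five-stage annealing tradition (liquid,
expansion, cooldown, crunch, simmer), each stage carrying a share of the
iteration budget (600 by default), a temperature, an attraction
multiplier, a density multiplier, and an edge-cutting flag. Per iteration
every node evaluates three candidate positions — stay, move to the
centroid of its neighbors, or take a random jump of magnitude
(temperature × initial radius) — and takes the lowest-energy one, where
energy is attraction × (sum of squared distances to current neighbors) +
ρ × (local density).

Numerical choices that matter:

* **Density grid.** $D$ is approximated on a fixed 64 × 64 occupancy grid
  over a world square of half-size $4\sqrt{N}$, Gaussian-smoothed
  (σ = 1.2 bins, radius 3). The *absolute* bin size is essential: a grid
  that rescaled to the current layout extent would let the attraction
  term contract the whole embedding to a point, since uniform shrinking
  would leave relative densities unchanged. With fixed bins, contraction
  raises density and halts — this is the only repulsion in the model.
  (`layout_objective()` reports the same objective with an edge-midpoint
  density grid at extent/64 resolution, the documented closed-form
  approximation of "density of the edges near $x_i$".)
* **Balance calibration.** ρ is set once, on the initial random
  configuration, to equalize the mean attraction and density energies,
  then modulated per stage (density weight 3 in expansion, fading to 0.2
  in simmer). A per-iteration re-calibration would reintroduce scale
  freedom and allow collapse.
* **Synchronous updates.** All nodes move simultaneously against the
  previous configuration. This is what lets a community collapse onto its
  own centroid in a few iterations and then travel as a unit under the
  density force; sequential or damped updates were markedly worse at
  separating planted populations in development, and are not used.
* **Edge cutting.** During the cooldown and crunch stages, edges longer
  than the $(1 - 0.4\,c)$ quantile of current edge lengths are ignored
  ($c$ = `edge_cut`, default 0.8), emulating the classic single-knob
  cutting heuristic: long edges are usually inter-community and ignoring
  them increases white space.
* **Determinism.** All randomness flows through a seeded RNG scope that
  restores the caller's RNG state; node and edge order are canonicalized
  before layout, so the result is invariant to input row order.
* **Degenerate inputs.** A single node is placed at the origin by
  convention; an empty graph errors.

The alternative `"drl"` backend delegates to igraph's DrL implementation
(same algorithm family, C speed) and satisfies the same separation
properties under the same seed discipline; the bespoke annealer is the
default because its schedule, objective and trace are fully inspectable.
The objective is monitored at stage boundaries (`objective_trace`
attribute); the long-run trend is non-increasing, though individual stage
transitions may rise when the density weight changes.

## Spatial zonation and coordinate prediction

Given a genes × bins matrix of probabilistic mapping scores and bin
coordinates (e.g. a virtual embryo), each cluster's spatial footprint is
scored by Stouffer combination: every gene's score vector is standardized
across bins (Stouffer's method requires z-scores; the mapping scores
arrive on arbitrary scales, so per-gene standardization is applied and
documented), then combined per bin as $\sum_g z_{gb}/\sqrt{G}$. Constant
score rows carry no positional information and are dropped with a
warning. Binarization is by explicit threshold; the convenience wrapper
`zonation_scores()` offers a quantile calibration (select as many bins as
the expected footprint fraction) in place of the manual threshold the
procedure otherwise requires. Cross-assay cluster correspondence is the
Pearson correlation of cluster-wise mean expression over a shared gene
panel. Coordinate prediction fits one decision tree per coordinate
(gene scores as predictors) on 50 bootstrap samples of the bins,
reporting out-of-bag RMSE next to the null RMSE of predicting the
training mean; the default tree is grown deep (minsplit 2, minbucket 1,
cp 0 — the defaults of the regressor the design names), which nails
noiseless signal but overfits pure noise by design; the pruned
alternative is one `control` argument away.

## The synthetic generator

`simulate_counts()` emulates UMI data: negative-binomial counts with
per-gene baseline means uniform on [0.5, 2] and dispersion 0.1–1
(default 0.3) — typical sparse droplet-like magnitudes — with each
cluster owning a disjoint block of marker genes whose mean is multiplied
by $2^{\mathrm{log2fc}}$ in that cluster, and an optional rare cluster.
`simulate_binmap()` places bins on an ellipse (embryo-like outline) and
gives each cluster's genes a Gaussian angular falloff around its own arc.
What these fixtures do *not* emulate: batch effects, doublets, ambient
RNA, gene–gene correlation beyond cluster structure, mean–variance trends
beyond the NB family, or irregular spatial geometries. Passing tests
therefore demonstrate algorithmic correctness and recovery under clean,
planted structure — not robustness to every artifact of real data.

Test and acceptance problem sizes are chosen to exercise every code path
at desk scale: the standard fixture is 1000 cells × 2000 genes with 5
clusters of 50 markers each (log2fc 2, dispersion 0.3), the fast fixture
300 × 600, the bin map 300 bins; oracle-equivalence checks run at ≤ 200
items where brute force is exact.

## Evaluation metrics

NMI uses the arithmetic-mean normalization of the two entropies (the
normalization is stated because several are in circulation); the
degenerate case of two single-cluster labelings is defined as 1. ARI is
the permutation-model adjustment of pair counting. Silhouette is computed
in whatever 2D space is supplied, with singleton clusters contributing 0
and noise points dropped. All three are invariant to label renaming and
are cross-checked in the tests against brute-force oracles and, for
silhouette and ARI, against the standard `cluster` and `mclust`
implementations.

## Known limitations

* The annealer is pure R; it is comfortable to a few thousand layout
  nodes (subsampling exists precisely to keep it there) but is not
  competitive with compiled DrL on very large graphs — switch
  `layout_backend = "drl"` for those.
* DBSCAN's knee calibration can merge genuinely adjacent populations on
  layouts without clear density valleys; `eps` and `min_samples` are
  exposed for manual control.
* Four passes are fixed. The pass log exposes between-pass ARI so users
  can see whether the clustering had stabilized by pass 3, but the loop
  does not currently stop early or extend itself.
* With subsampling enabled, marker statistics are computed on all labeled
  cells (sampled + post hoc), so borderline cells assigned by majority
  vote contribute to DE.
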