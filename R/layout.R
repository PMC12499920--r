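# OpenOrd-style force-directed layout of the cell-gene network.
#
# The layout minimizes sum_i ( sum_j w_ij * d(x_i, x_j)^2 + D_{x_i} ) with
# unit edge weights, where D is the local density near x_i, by simulated
# annealing over a five-stage schedule (liquid, expansion, cooldown,
# crunch, simmer). Two backends satisfy the same contract: the bespoke
# annealer below, and igraph's DrL implementation.

#' Annealing stage schedule
#'
#' Five-stage schedule in the OpenOrd tradition. Each stage carries its
#' share of the iteration budget, a temperature (random-jump magnitude as a
#' fraction of the layout extent, interpolated linearly across the stage),
#' an attraction multiplier, a density (repulsion) multiplier, and whether
#' the edge-cutting heuristic is active.
#'
#' @param n_iter Total iteration budget (default 600).
#' @param liquid,expansion,cooldown,crunch,simmer Per-stage overrides: named
#'   lists with any of `frac`, `temp_start`, `temp_end`, `attraction`,
#'   `density`, `cut`.
#' @return A data frame with one row per stage.
#' @export
openord_schedule <- function(n_iter = 600, liquid = list(), expansion = list(),
                             cooldown = list(), crunch = list(),
                             simmer = list()) {
  base <- list(
    liquid    = list(frac = 0.20, temp_start = 0.40, temp_end = 0.40,
                     attraction = 1,   density = 1.0, cut = FALSE),
    expansion = list(frac = 0.25, temp_start = 0.30, temp_end = 0.15,
                     attraction = 1,   density = 3.0, cut = FALSE),
    cooldown  = list(frac = 0.25, temp_start = 0.15, temp_end = 0.05,
                     attraction = 2,   density = 1.0, cut = TRUE),
    crunch    = list(frac = 0.10, temp_start = 0.02, temp_end = 0.02,
                     attraction = 4,   density = 0.5, cut = TRUE),
    simmer    = list(frac = 0.20, temp_start = 0.01, temp_end = 0.0,
                     attraction = 2,   density = 0.2, cut = FALSE)
  )
  for (nm in names(base)) {
    ov <- get(nm)
    for (f in names(ov)) base[[nm]][[f]] <- ov[[f]]
  }
  df <- do.call(rbind, lapply(names(base), function(nm) {
    s <- base[[nm]]
    data.frame(stage = nm, iter = max(1L, as.integer(round(s$frac * n_iter))),
               temp_start = s$temp_start, temp_end = s$temp_end,
               attraction = s$attraction, density = s$density, cut = s$cut)
  }))
  df
}

# Separable Gaussian smoothing of an occupancy grid (kernel radius 3 bins).
smooth_grid <- function(g, sigma = 1.2) {
  k <- exp(-(-3:3)^2 / (2 * sigma^2)); k <- k / sum(k)
  sm1 <- function(m) {
    out <- m * k[4]
    for (d in 1:3) {
      nr <- nrow(m)
      up <- rbind(m[-seq_len(d), , drop = FALSE],
                  matrix(0, d, ncol(m)))
      dn <- rbind(matrix(0, d, ncol(m)),
                  m[seq_len(nr - d), , drop = FALSE])
      out <- out + k[4 + d] * up + k[4 - d] * dn
    }
    out
  }
  t(sm1(t(sm1(g))))
}

# Occupancy-grid density: counts of points per bin, Gaussian-smoothed.
# Returns a lookup closure mapping positions to density values.
grid_density <- function(pts, nbins = 64, bin = NULL) {
  rx <- range(pts[, 1]); ry <- range(pts[, 2])
  ext <- max(rx[2] - rx[1], ry[2] - ry[1], 1e-9)
  if (!is.null(bin)) nbins <- max(2L, as.integer(ceiling(ext / bin)))
  ix <- pmin(nbins, pmax(1L, as.integer(ceiling((pts[, 1] - rx[1]) / ext * nbins))))
  iy <- pmin(nbins, pmax(1L, as.integer(ceiling((pts[, 2] - ry[1]) / ext * nbins))))
  g <- matrix(0, nbins, nbins)
  tab <- table(factor(ix, levels = seq_len(nbins)),
               factor(iy, levels = seq_len(nbins)))
  g[] <- as.numeric(tab)
  g <- smooth_grid(g)
  function(q) {
    qx <- pmin(nbins, pmax(1L, as.integer(ceiling((q[, 1] - rx[1]) / ext * nbins))))
    qy <- pmin(nbins, pmax(1L, as.integer(ceiling((q[, 2] - ry[1]) / ext * nbins))))
    g[cbind(qx, qy)]
  }
}

#' Layout objective of an embedding
#'
#' Evaluates the attraction-plus-density objective of the layout: the sum
#' over edges of squared Euclidean distance (unit weights) plus the sum
#' over nodes of the local edge density. The density term is a documented
#' approximation: edge midpoints are binned on a fixed-resolution occupancy
#' grid (bin width `grid_bin`, default extent/64) with Gaussian smoothing,
#' and each node contributes the smoothed density at its own position.
#'
#' @param graph A `stardust_graph`.
#' @param emb An embedding tibble covering all graph nodes.
#' @param grid_bin Density grid bin width (default: layout extent / 64).
#' @return A list with `attraction`, `density`, and `total`.
#' @export
layout_objective <- function(graph, emb, grid_bin = NULL) {
  missing <- setdiff(graph$nodes$node_id, emb$node_id)
  if (length(missing)) {
    abort(paste0("embedding lacks coordinates for: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  pos <- as.matrix(emb[, c("x", "y")])
  rownames(pos) <- emb$node_id
  a <- pos[graph$edges$from, , drop = FALSE]
  b <- pos[graph$edges$to, , drop = FALSE]
  d2 <- rowSums((a - b)^2)
  attraction <- sum(d2)
  if (nrow(graph$edges) > 0) {
    mid <- (a + b) / 2
    dens <- grid_density(mid, bin = grid_bin)
    density <- sum(dens(pos))
  } else {
    density <- 0
  }
  list(attraction = attraction, density = density,
       total = attraction + density)
}

#' Force-directed layout of a cell-gene network
#'
#' Computes 2D coordinates for every node (cells and genes alike) of the
#' heterogeneous network. The default backend is a bespoke simulated
#' annealer over the attraction-plus-density objective with the
#' [openord_schedule()] stages and an edge-cutting heuristic (`edge_cut` in
#' \[0, 1\]: 0 = never ignore an edge, 1 = aggressively ignore the longest
#' edges during the cutting stages, increasing white space between
#' clusters). The `"drl"` backend delegates to igraph's DrL layout, the
#' common library implementation of the same algorithm family. Both
#' backends are deterministic for a fixed seed.
#'
#' @param graph A validated `stardust_graph`.
#' @param seed Integer seed.
#' @param edge_cut Edge-cutting strength in \[0, 1\] (default 0.8).
#' @param schedule Stage schedule from [openord_schedule()].
#' @param backend `"openord"` (bespoke annealer, default) or `"drl"`
#'   (igraph DrL).
#' @return Embedding tibble: `node_id`, `node_type`, `x`, `y`; attributes
#'   `seed`, `edge_cut`, and (openord backend) `objective_trace`, the
#'   objective evaluated at stage boundaries.
#' @export
layout_graph <- function(graph, seed = 1, edge_cut = 0.8,
                         schedule = openord_schedule(),
                         backend = c("openord", "drl")) {
  backend <- match.arg(backend)
  validate_graph(graph)
  # canonical node/edge order: the layout depends on the graph, not on the
  # order its rows arrived in
  graph$nodes <- graph$nodes[order(graph$nodes$node_id, method = "radix"), ]
  graph$edges <- graph$edges[order(graph$edges$from, graph$edges$to,
                                   method = "radix"), ]
  n <- nrow(graph$nodes)
  if (n == 0) abort("cannot lay out an empty graph.")
  ids <- graph$nodes$node_id
  if (n == 1) {
    pos <- matrix(0, 1, 2)
  } else if (backend == "drl") {
    ig <- as_igraph(graph)
    opts <- igraph::drl_defaults$default
    opts$edge.cut <- edge_cut
    pos <- with_seed(seed, igraph::layout_with_drl(ig, options = opts))
    pos <- pos[match(ids, igraph::V(ig)$name), , drop = FALSE]
  } else {
    idx <- setNames(seq_len(n), ids)
    ei <- c(idx[graph$edges$from], idx[graph$edges$to])
    ej <- c(idx[graph$edges$to], idx[graph$edges$from])
    pos <- anneal_layout(n, ei, ej, seed = seed, edge_cut = edge_cut,
                         schedule = schedule)
  }
  emb <- tibble(node_id = ids, node_type = graph$nodes$node_type,
                x = pos[, 1], y = pos[, 2])
  attr(emb, "seed") <- seed
  attr(emb, "edge_cut") <- edge_cut
  if (backend == "openord" && n > 1) {
    attr(emb, "objective_trace") <- attr(pos, "objective_trace")
  }
  emb
}

# The bespoke annealer. ei/ej are directed edge endpoints (both directions
# of every undirected edge), 1-based node indices.
#
# The density grid lives on a fixed world square (half-size 4*sqrt(n)); the
# absolute bin size is what stops the attraction term from contracting the
# whole layout to a point. The attraction/density balance rho is calibrated
# once on the initial random configuration and then only modulated by the
# per-stage density multiplier.
anneal_layout <- function(n, ei, ej, seed, edge_cut, schedule) {
  with_seed(seed, {
    r0 <- sqrt(n)
    L <- 4 * r0
    th <- runif(n, 0, 2 * pi); rr <- r0 * sqrt(runif(n))
    x <- cbind(rr * cos(th), rr * sin(th))
    deg_all <- tabulate(ei, n)
    a0 <- anneal_attraction(x, n, ei, ej, x)
    d0 <- fixed_density(x, L)(x)
    rho0 <- (mean(a0) + 1e-12) / (mean(d0) + 1e-12)
    trace <- numeric(0)
    for (s in seq_len(nrow(schedule))) {
      st <- schedule[s, ]
      temps <- seq(st$temp_start, st$temp_end, length.out = st$iter)
      for (it in seq_len(st$iter)) {
        x <- anneal_step(x, n, ei, ej, L = L, r0 = r0, temp = temps[it],
                         attraction = st$attraction,
                         rho = rho0 * st$density,
                         cut = st$cut, edge_cut = edge_cut)
      }
      trace <- c(trace, anneal_energy(x, n, ei, ej, L))
    }
    attr(x, "objective_trace") <- trace
    x
  })
}

# Total attraction + node-density energy (monitoring only).
anneal_energy <- function(x, n, ei, ej, L) {
  d2 <- rowSums((x[ei, , drop = FALSE] - x[ej, , drop = FALSE])^2)
  sum(d2) / 2 + sum(fixed_density(x, L)(x))
}

# Occupancy density on the fixed world square [-L, L]^2.
fixed_density <- function(pts, L, nbins = 64) {
  to_bin <- function(v) pmin(nbins, pmax(1L, as.integer(
    ceiling((v + L) / (2 * L) * nbins))))
  g <- matrix(0, nbins, nbins)
  tab <- table(factor(to_bin(pts[, 1]), levels = seq_len(nbins)),
               factor(to_bin(pts[, 2]), levels = seq_len(nbins)))
  g[] <- as.numeric(tab)
  g <- smooth_grid(g)
  function(q) g[cbind(to_bin(q[, 1]), to_bin(q[, 2]))]
}

# Per-node attraction energy of candidate positions y against the current
# configuration x: sum over neighbors of squared distance.
anneal_attraction <- function(y, n, ei, ej, x, act = NULL) {
  if (!is.null(act)) { ei <- ei[act]; ej <- ej[act] }
  deg <- tabulate(ei, n)
  S <- rowsum_n(x[ej, , drop = FALSE], ei, n)
  q <- rowSums(x^2)
  sq_nb <- rowsum_n(cbind(q[ej]), ei, n)[, 1]
  deg * rowSums(y^2) - 2 * rowSums(y * S) + sq_nb
}

anneal_step <- function(x, n, ei, ej, L, r0, temp, attraction, rho, cut,
                        edge_cut) {
  act <- NULL
  if (cut && edge_cut > 0) {
    len2 <- rowSums((x[ei, , drop = FALSE] - x[ej, , drop = FALSE])^2)
    thr <- quantile(len2, probs = max(0, 1 - 0.4 * edge_cut))
    act <- len2 <= thr
  }
  eia <- if (is.null(act)) ei else ei[act]
  eja <- if (is.null(act)) ej else ej[act]
  deg <- tabulate(eia, n)
  S <- rowsum_n(x[eja, , drop = FALSE], eia, n)
  q <- rowSums(x^2)
  sq_nb <- rowsum_n(cbind(q[eja]), eia, n)[, 1]
  # candidate positions: stay, neighbor centroid, random jump
  cand_cent <- S / pmax(deg, 1)
  cand_cent[deg == 0, ] <- x[deg == 0, ]
  jt <- runif(n, 0, 2 * pi); jr <- temp * r0 * sqrt(runif(n))
  cand_jump <- x + cbind(jr * cos(jt), jr * sin(jt))
  dens <- fixed_density(x, L)
  attr_of <- function(y) deg * rowSums(y^2) - 2 * rowSums(y * S) + sq_nb
  e_stay <- attraction * attr_of(x) + rho * dens(x)
  e_cent <- attraction * attr_of(cand_cent) + rho * dens(cand_cent)
  e_jump <- attraction * attr_of(cand_jump) + rho * dens(cand_jump)
  best <- max.col(-cbind(e_stay, e_cent, e_jump), ties.method = "first")
  y <- x
  y[best == 2, ] <- cand_cent[best == 2, , drop = FALSE]
  y[best == 3, ] <- cand_jump[best == 3, , drop = FALSE]
  pmin(pmax(y, -L), L)
}

# rowsum with guaranteed n rows (missing groups filled with zero).
rowsum_n <- function(m, idx, n) {
  out <- matrix(0, n, ncol(m))
  rs <- rowsum(m, idx)
  out[as.integer(rownames(rs)), ] <- rs
  out
}
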