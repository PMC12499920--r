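# Independent brute-force oracles, kept free of any package internals.

# DBSCAN density reachability: core points from the full distance matrix,
# clusters as connected components of the core-core eps-graph, border
# points attach to any cluster owning a core neighbor.
dbscan_oracle <- function(pos, eps, min_pts) {
  d <- as.matrix(stats::dist(pos))
  nb <- lapply(seq_len(nrow(pos)), function(i) which(d[i, ] <= eps + 1e-12))
  core <- vapply(nb, length, integer(1)) >= min_pts
  n <- nrow(pos)
  lab <- rep(-1L, n)
  cl <- 0L
  for (i in which(core)) {
    if (lab[i] != -1L) next
    cl <- cl + 1L
    frontier <- i
    lab[i] <- cl
    while (length(frontier)) {
      nxt <- unique(unlist(nb[frontier]))
      nxt <- nxt[core[nxt] & lab[nxt] == -1L]
      lab[nxt] <- cl
      frontier <- nxt
    }
  }
  border_choices <- lapply(seq_len(n), function(i) {
    if (core[i] || lab[i] != -1L) return(integer())
    unique(lab[nb[[i]][core[nb[[i]]]]])
  })
  list(labels = lab, core = core, border_choices = border_choices)
}

# Overestimated-variance t statistic: both variance terms divided by the
# focal group's size, Welch-Satterthwaite degrees of freedom.
t_overestim_oracle <- function(g, r) {
  ng <- length(g)
  se <- sqrt(var(g) / ng + var(r) / ng)
  t <- (mean(g) - mean(r)) / se
  df <- (var(g) / ng + var(r) / ng)^2 /
    ((var(g) / ng)^2 / (ng - 1) + (var(r) / ng)^2 / (length(r) - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# Benjamini-Hochberg by sort and cumulative minimum from the largest p.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

nmi_oracle <- function(a, b) {
  n <- length(a)
  pa <- table(a) / n; pb <- table(b) / n
  h <- function(p) -sum(p * log(p))
  mi <- 0
  for (i in names(pa)) for (j in names(pb)) {
    pij <- sum(a == i & b == j) / n
    if (pij > 0) mi <- mi + pij * log(pij / (pa[[i]] * pb[[j]]))
  }
  if (h(pa) == 0 && h(pb) == 0) return(1)
  if ((h(pa) + h(pb)) == 0) return(0)
  mi / ((h(pa) + h(pb)) / 2)
}

ari_oracle <- function(a, b) {
  n <- length(a)
  s_ab <- 0; s_a <- 0; s_b <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same_a <- a[i] == a[j]; same_b <- b[i] == b[j]
    if (same_a && same_b) s_ab <- s_ab + 1
    if (same_a) s_a <- s_a + 1
    if (same_b) s_b <- s_b + 1
  }
  tot <- choose(n, 2)
  exp_idx <- s_a * s_b / tot
  max_idx <- (s_a + s_b) / 2
  if (max_idx == exp_idx) return(1)
  (s_ab - exp_idx) / (max_idx - exp_idx)
}

silhouette_oracle <- function(pos, lab) {
  d <- as.matrix(stats::dist(pos))
  n <- nrow(pos)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(lab == lab[i] & seq_len(n) != i)
    if (length(own) == 0) { s[i] <- 0; next }
    a_i <- mean(d[i, own])
    b_i <- Inf
    for (cl in setdiff(unique(lab), lab[i])) {
      b_i <- min(b_i, mean(d[i, lab == cl]))
    }
    s[i] <- if (max(a_i, b_i) == 0) 0 else (b_i - a_i) / max(a_i, b_i)
  }
  mean(s)
}

# K-nearest-neighbor regression by exhaustive search: mean response of the
# K nearest training points.
knn_reg_oracle <- function(train_x, train_y, query, K) {
  t(apply(query, 1, function(q) {
    d <- sqrt(colSums((t(train_x) - q)^2))
    colMeans(train_y[order(d)[seq_len(K)], , drop = FALSE])
  }))
}
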