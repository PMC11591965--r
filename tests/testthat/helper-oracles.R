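# Independent brute-force oracles. These deliberately avoid the package's
# (and igraph's) algorithms: direct formula evaluation, Floyd-Warshall plus
# recursive path enumeration, and exhaustive labeling search.

# Direct evaluation of the cross-correlation definition, one pair at a time.
oracle_dccm <- function(coords) {
  nf <- dim(coords)[1]; n <- dim(coords)[2]
  mu <- apply(coords, c(2, 3), mean)
  C <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    num <- 0; di <- 0; dj <- 0
    for (t in 1:nf) {
      a <- coords[t, i, ] - mu[i, ]
      b <- coords[t, j, ] - mu[j, ]
      num <- num + sum(a * b)
      di <- di + sum(a * a)
      dj <- dj + sum(b * b)
    }
    C[i, j] <- num / sqrt(di * dj)
  }
  C
}

# All-pairs shortest paths (Floyd-Warshall) on a weight matrix with Inf for
# missing edges.
oracle_distances <- function(W) {
  n <- nrow(W); d <- W; diag(d) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Number of shortest s->t paths, by recursion over the shortest-path DAG.
oracle_n_paths <- function(W, d, s, t, tol = 1e-10) {
  if (s == t) return(1)
  if (!is.finite(d[s, t])) return(0)
  total <- 0
  for (u in seq_len(nrow(W))) {
    if (u != s && is.finite(W[s, u]) &&
        abs(W[s, u] + d[u, t] - d[s, t]) <= tol)
      total <- total + oracle_n_paths(W, d, u, t, tol)
  }
  total
}

# The three centralities by exhaustive enumeration.
oracle_centralities <- function(W, tol = 1e-10) {
  n <- nrow(W)
  d <- oracle_distances(W)
  np <- matrix(0, n, n)
  for (s in 1:n) for (t in 1:n) np[s, t] <- oracle_n_paths(W, d, s, t, tol)
  clo <- numeric(n)
  for (i in 1:n) {
    comp <- which(is.finite(d[i, ]))  # includes i
    clo[i] <- if (length(comp) == 1L) 0
              else (length(comp) - 1) / sum(d[i, setdiff(comp, i)])
  }
  btw <- numeric(n)
  for (i in 1:n) {
    acc <- 0
    for (s in 1:(n - 1)) for (t in (s + 1):n) {
      if (s == i || t == i || !is.finite(d[s, t])) next
      if (abs(d[s, i] + d[i, t] - d[s, t]) <= tol)
        acc <- acc + np[s, i] * np[i, t] / np[s, t]
    }
    btw[i] <- acc / (n * (n - 1) / 2)
  }
  deg <- rowSums(is.finite(W) & upper.tri(W) | is.finite(W) & lower.tri(W))
  list(closeness = clo, betweenness = btw, degree = as.integer(deg))
}

# Random correlation-style matrix whose implied graph has the given edge
# density; edge |C| values in (cutoff, cmax) so edges are unambiguous.
random_graph_dccm <- function(n, p_edge = 0.5, cutoff = 0.3, cmax = 0.95) {
  C <- diag(n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p_edge) {
      v <- runif(1, cutoff + 0.05, cmax) * sample(c(-1, 1), 1)
      C[i, j] <- C[j, i] <- v
    }
  }
  rownames(C) <- colnames(C) <- as.character(seq_len(n))
  C
}

weight_matrix <- function(graph) {
  n <- length(graph$nodes)
  W <- matrix(Inf, n, n, dimnames = list(graph$nodes, graph$nodes))
  if (nrow(graph$edges))
    for (e in seq_len(nrow(graph$edges))) {
      i <- match(graph$edges$i[e], graph$nodes)
      j <- match(graph$edges$j[e], graph$nodes)
      W[i, j] <- W[j, i] <- graph$edges$weight[e]
    }
  W
}

# Minimum substitutions over all internal (and missing-leaf) labelings.
oracle_fitch <- function(tree, leaf_states, alphabet) {
  tr <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- length(tr$tip.label)
  n_nodes <- n_tip + tr$Nnode
  A <- length(alphabet)
  fixed <- match(leaf_states[tr$tip.label], alphabet)  # NA = missing/gap
  labeling <- rep(NA_integer_, n_nodes)
  labeling[seq_len(n_tip)] <- fixed
  free <- which(is.na(labeling))  # internal nodes and missing leaves
  best <- Inf
  grid <- rep(list(seq_len(A)), length(free))
  combos <- do.call(expand.grid, grid)
  for (r in seq_len(nrow(combos))) {
    lab <- labeling
    lab[free] <- as.integer(combos[r, ])
    cost <- sum(lab[tr$edge[, 1]] != lab[tr$edge[, 2]])
    if (cost < best) best <- cost
  }
  best
}

# Adaptive quadrature of the gamma-Poisson mixture integrals.
oracle_Q_quad <- function(i, alpha, beta, T) {
  stats::integrate(function(l) stats::dpois(i, l * T) *
                     stats::dgamma(l, alpha, rate = beta),
                   0, Inf, rel.tol = 1e-12, abs.tol = 1e-13,
                   subdivisions = 500L)$value
}

oracle_K12_quad <- function(i, j, alpha, beta, T1, T2) {
  stats::integrate(function(l) stats::dpois(i, l * T1) *
                     stats::dpois(j, l * T2) *
                     stats::dgamma(l, alpha, rate = beta),
                   0, Inf, rel.tol = 1e-12, abs.tol = 1e-13,
                   subdivisions = 500L)$value
}

# Wrap a trajectory whose frames already share a reference frame as a
# superposition, bypassing the rigid-body fit.
raw_sup <- function(traj) {
  structure(list(aligned = traj,
                 reference = traj$coords[1, , ],
                 per_frame_rmsd = rep(0, dim(traj$coords)[1])),
            class = "superposition")
}

# Random tree with strictly positive branch lengths and its additive
# (path-length) distance matrix.
random_additive_tree <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(k) runif(k, 0.1, 1))
  d <- ape::cophenetic.phylo(tr)
  ord <- order(rownames(d))
  list(tree = tr, d = d[ord, ord])
}
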