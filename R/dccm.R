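#' Dynamic cross-correlation map
#'
#' Computes the DCCM of a superposed trajectory:
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)`, where
#' `dr_i(t) = r_i(t) - <r_i>` is the displacement of residue i from its
#' time-average position and the dot product runs over x, y, z. `C_ij = 1`
#' is fully correlated motion, `-1` fully anti-correlated.
#'
#' @param sup a [superpose()] result with at least two frames, or a
#'   [trajectory()] whose frames are already expressed in a common
#'   reference frame (e.g. the output of [simulate_trajectory()], which
#'   adds no global motion); real trajectories should be superposed first.
#' @return An object of class `dccm_map`: a symmetric `N x N` matrix with
#'   unit diagonal, with attribute `residue_ids`.
#' @export
compute_dccm <- function(sup) {
  if (inherits(sup, "trajectory")) sup <- list(aligned = sup)
  else stopifnot(inherits(sup, "superposition"))
  co <- sup$aligned$coords
  if (dim(co)[1] < 2L) stop_nd("DCCM needs at least 2 frames")
  nf <- dim(co)[1]
  # <dr_i . dr_j> = (Ax'Ax + Ay'Ay + Az'Az)/T on centered per-axis matrices
  num <- matrix(0, dim(co)[2], dim(co)[2])
  for (k in 1:3) {
    A <- scale(co[, , k], scale = FALSE)
    num <- num + crossprod(A)
  }
  num <- num / nf
  d <- diag(num)
  if (any(d <= 0)) {
    bad <- residue_labels(sup$aligned)[which(d <= 0)[1]]
    stop_nd("residue ", bad, " has zero fluctuation; DCCM undefined")
  }
  C <- num / sqrt(outer(d, d))
  C <- pmin(pmax(C, -1), 1)
  C <- (C + t(C)) / 2
  diag(C) <- 1
  labs <- residue_labels(sup$aligned)
  dimnames(C) <- list(labs, labs)
  structure(C, class = c("dccm_map", "matrix"),
            residue_ids = sup$aligned$residue_ids)
}

#' @export
print.dccm_map <- function(x, ...) {
  off <- x[upper.tri(x)]
  cat(sprintf("<dccm_map> %d residues; off-diagonal C in [%.3f, %.3f]\n",
              nrow(x), min(off), max(off)))
  invisible(x)
}

#' Build the weighted residue interaction network
#'
#' Residues are nodes; an edge joins i and j (i != j) exactly when
#' `|C_ij| >= correlation_cutoff`. Edge weights are
#' `w_ij = -log(|C_ij|) >= 0`, so strongly correlated pairs are "close" and
#' shortest paths trace chains of correlated motion. Anti-correlated pairs
#' are treated as communicating with equal strength (the absolute value).
#' The 0/1 adjacency used by degree centrality marks the same edge set.
#'
#' @param dccm a [compute_dccm()] result (or plain symmetric matrix).
#' @param correlation_cutoff edge threshold on `|C_ij|`, in (0, 1).
#'   Default 0.5.
#' @param weight_log_base base of the logarithm in the edge weight;
#'   the natural log (`exp(1)`, default) is the information-theoretic
#'   convention.
#' @return An object of class `residue_graph`: `nodes` (labels), `edges`
#'   (data frame `i, j, cor, weight`), `adjacency` (0/1 matrix), `cutoff`,
#'   and `residue_ids`.
#' @export
build_graph <- function(dccm, correlation_cutoff = 0.5,
                        weight_log_base = exp(1)) {
  check_number(correlation_cutoff, "correlation_cutoff")
  if (correlation_cutoff <= 0 || correlation_cutoff >= 1)
    stop_nd("'correlation_cutoff' must be strictly inside (0, 1), got ",
            correlation_cutoff)
  check_number(weight_log_base, "weight_log_base", lower = 1 + 1e-12)
  C <- unclass(dccm)
  check_symmetric(C, "dccm", tol = 1e-9)
  n <- nrow(C)
  labs <- rownames(C) %||% as.character(seq_len(n))
  A <- (abs(C) >= correlation_cutoff) * 1L
  diag(A) <- 0L
  idx <- which(upper.tri(A) & A == 1L, arr.ind = TRUE)
  edges <- data.frame(i = labs[idx[, 1]], j = labs[idx[, 2]],
                      cor = C[idx],
                      weight = -log(abs(C[idx]), base = weight_log_base),
                      stringsAsFactors = FALSE)
  dimnames(A) <- list(labs, labs)
  structure(list(nodes = labs, edges = edges, adjacency = A,
                 cutoff = correlation_cutoff,
                 residue_ids = attr(dccm, "residue_ids")),
            class = "residue_graph")
}

#' @export
print.residue_graph <- function(x, ...) {
  cat(sprintf("<residue_graph> %d nodes, %d edges (|C| >= %.2f)\n",
              length(x$nodes), nrow(x$edges), x$cutoff))
  invisible(x)
}

as_igraph <- function(graph) {
  g <- igraph::graph_from_data_frame(graph$edges[, c("i", "j")],
                                     directed = FALSE,
                                     vertices = data.frame(name = graph$nodes))
  igraph::E(g)$weight <- graph$edges$weight
  g
}

#' Closeness centrality
#'
#' `CC(v) = (n - 1) / sum_j g(v, v_j)` with `g` the weighted shortest-path
#' length. On a disconnected graph each node is scored within its own
#' connected component (`n` = component size); isolated nodes score 0.
#'
#' @param graph a [build_graph()] result.
#' @return named numeric vector over nodes.
#' @export
closeness_centrality <- function(graph) {
  stopifnot(inherits(graph, "residue_graph"))
  g <- as_igraph(graph)
  cc <- suppressWarnings(
    igraph::closeness(g, normalized = TRUE, weights = igraph::E(g)$weight))
  cc[!is.finite(cc)] <- 0
  setNames(as.numeric(cc), graph$nodes)
}

#' Betweenness centrality
#'
#' Fraction of shortest paths mediated by a node:
#' `b_i = [sum_{s<t} g_ist / n_st] / [n (n - 1) / 2]`, where `g_ist` counts
#' the weighted shortest s-t paths through i (endpoints excluded), `n_st`
#' all shortest s-t paths, and `n` the total node count, so `b_i` lies in
#' \[0, 1\].
#'
#' @param graph a [build_graph()] result.
#' @return named numeric vector over nodes.
#' @export
betweenness_centrality <- function(graph) {
  stopifnot(inherits(graph, "residue_graph"))
  n <- length(graph$nodes)
  g <- as_igraph(graph)
  b <- igraph::betweenness(g, directed = FALSE, weights = igraph::E(g)$weight)
  setNames(as.numeric(b) / (n * (n - 1) / 2), graph$nodes)
}

#' Degree centrality
#'
#' Number of network edges incident on each node: `C_D(v_i) = sum_j A_ij`.
#'
#' @param graph a [build_graph()] result.
#' @return named integer vector over nodes.
#' @export
degree_centrality <- function(graph) {
  stopifnot(inherits(graph, "residue_graph"))
  setNames(as.integer(rowSums(graph$adjacency)), graph$nodes)
}

#' Centrality table
#'
#' All three centrality measures for every node, with per-measure dense
#' ranks (rank 1 = most central).
#'
#' @param graph a [build_graph()] result.
#' @return data frame with columns `node`, `betweenness`, `closeness`,
#'   `degree` and `rank_*` columns; class `centrality_table`.
#' @export
centrality_table <- function(graph) {
  bt <- betweenness_centrality(graph)
  cl <- closeness_centrality(graph)
  dg <- degree_centrality(graph)
  out <- data.frame(node = graph$nodes, betweenness = bt, closeness = cl,
                    degree = dg, row.names = NULL, stringsAsFactors = FALSE)
  for (m in c("betweenness", "closeness", "degree"))
    out[[paste0("rank_", m)]] <- rank(-out[[m]], ties.method = "min")
  class(out) <- c("centrality_table", "data.frame")
  out
}

# residue number extracted from a node label like "ALA 207" or "12"
node_resno <- function(labels) {
  num <- suppressWarnings(as.numeric(sub("^.*?(-?[0-9]+)[^0-9]*$", "\\1", labels)))
  ifelse(is.na(num), seq_along(labels), num)
}

#' Top-k residues per centrality measure
#'
#' Orders nodes by descending centrality (ties broken by ascending residue
#' number) and reports the first `k` per measure, plus the set of residues
#' that appear in the top `k` of every measure (the usual "overlap" residues
#' highlighted in centrality tables).
#'
#' @param table a [centrality_table()].
#' @param k how many residues per measure (default 15).
#' @return list with elements `betweenness`, `closeness`, `degree`
#'   (character vectors of node labels, best first) and `overlap`.
#' @export
rank_top <- function(table, k = 15L) {
  stopifnot(inherits(table, "centrality_table"))
  check_count(k, "k")
  resno <- node_resno(table$node)
  pick <- function(values) {
    ord <- order(-values, resno)
    table$node[ord][seq_len(min(k, nrow(table)))]
  }
  out <- list(betweenness = pick(table$betweenness),
              closeness = pick(table$closeness),
              degree = pick(table$degree))
  out$overlap <- Reduce(intersect, out)
  out
}
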