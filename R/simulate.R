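#' Specification for a synthetic correlated-fluctuation trajectory
#'
#' Describes a Gaussian stand-in for an MD trajectory: residues fluctuate
#' around a fixed mean structure with isotropic displacements whose
#' residue-residue correlation matrix is prescribed. The same correlation
#' is applied independently to the x, y and z displacement components, so
#' the dot-product cross-correlation of the simulated trajectory converges
#' to `target_correlation` as the number of frames grows.
#'
#' @param n_residues number of residues (>= 1).
#' @param n_frames number of frames (>= 2).
#' @param target_correlation symmetric positive semidefinite matrix with
#'   unit diagonal (defaults to the identity: independent residues).
#' @param fluctuation_scale RMS displacement per axis, Angstrom.
#' @param seed RNG seed.
#' @return object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(n_residues, n_frames,
                            target_correlation = NULL,
                            fluctuation_scale = 1.0, seed = 1L) {
  n_residues <- check_count(n_residues, "n_residues")
  n_frames <- check_count(n_frames, "n_frames", lower = 2L)
  check_number(fluctuation_scale, "fluctuation_scale", lower = 1e-12)
  if (is.null(target_correlation)) target_correlation <- diag(n_residues)
  check_symmetric(target_correlation, "target_correlation")
  if (nrow(target_correlation) != n_residues)
    stop_nd("'target_correlation' must be n_residues x n_residues")
  if (max(abs(diag(target_correlation) - 1)) > 1e-8)
    stop_nd("'target_correlation' must have unit diagonal")
  if (max(abs(target_correlation)) > 1 + 1e-8)
    stop_nd("'target_correlation' entries must lie in [-1, 1]")
  ev <- eigen(target_correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(ev))
    stop_nd("'target_correlation' is not positive semidefinite ",
            sprintf("(min eigenvalue %.3g)", min(ev)))
  structure(list(n_residues = n_residues, n_frames = n_frames,
                 target_correlation = target_correlation,
                 fluctuation_scale = fluctuation_scale,
                 seed = as.integer(seed)),
            class = "trajectory_spec")
}

#' Simulate a trajectory with prescribed cross-correlation
#'
#' Draws `n_frames` independent frames. Each frame displaces every residue
#' from a fixed globular mean structure (points spread on a sphere at
#' C-alpha-like 3.8 Angstrom spacing, so the shape is compact and rigid-body
#' fits are well conditioned) by a zero-mean Gaussian vector whose per-axis
#' covariance across residues is
#' `fluctuation_scale^2 * target_correlation`. All frames share this
#' reference frame: no global rotation or translation is added, so the
#' sample DCCM of the raw coordinates converges to the target as the number
#' of frames grows. Identical specs give identical output.
#'
#' @param spec a [trajectory_spec()].
#' @return a [trajectory()].
#' @export
simulate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  n <- spec$n_residues; nf <- spec$n_frames
  e <- eigen(spec$target_correlation, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), n)  # C = L L'
  base_xyz <- sphere_points(n, spacing = 3.8)
  coords <- with_seed(spec$seed, {
    a <- array(0, c(nf, n, 3L))
    for (k in 1:3) {
      Z <- matrix(rnorm(nf * n), nf, n)
      disp <- spec$fluctuation_scale * (Z %*% t(L))
      a[, , k] <- matrix(base_xyz[, k], nf, n, byrow = TRUE) + disp
    }
    a
  })
  trajectory(coords)
}

# NB: loadings give hub-member correlation rho and member-member rho^2,
# so with rho just above a network cutoff each hub group is a star.

# Deterministic compact 3D arrangement: Fibonacci lattice on a sphere whose
# radius gives roughly `spacing` between neighbouring points.
sphere_points <- function(n, spacing = 3.8) {
  if (n == 1L) return(matrix(0, 1L, 3L))
  radius <- spacing * sqrt(n / (4 * pi))
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Hub-structured target correlation matrix
#'
#' A positive-semidefinite correlation matrix built from a latent-factor
#' model in which each designated hub residue *is* a collective-motion
#' factor: non-hub residues are assigned round-robin to one hub and load on
#' it with `sqrt(rho)`, so hub-to-member correlation is `rho`,
#' member-to-member correlation within a hub group is `rho^2`, and
#' cross-group correlation is 0. Useful for planting network hubs with a
#' known answer.
#'
#' @param n_residues total residues.
#' @param hubs indices of the hub residues.
#' @param rho hub-member correlation (0 < rho < 1).
#' @return `n_residues x n_residues` correlation matrix, PSD by
#'   construction.
#' @export
hub_correlation <- function(n_residues, hubs, rho = 0.6) {
  check_number(rho, "rho", lower = 1e-6, upper = 1 - 1e-6)
  stopifnot(all(hubs >= 1), all(hubs <= n_residues))
  members <- setdiff(seq_len(n_residues), hubs)
  group <- integer(n_residues)
  group[hubs] <- seq_along(hubs)
  group[members] <- rep_len(seq_along(hubs), length(members))
  # loadings on one factor per hub
  Lo <- matrix(0, n_residues, length(hubs))
  Lo[cbind(hubs, seq_along(hubs))] <- 1
  Lo[cbind(members, group[members])] <- rho
  C <- Lo %*% t(Lo)
  diag(C) <- 1
  C
}

#' Specification for a synthetic two-cluster alignment
#'
#' Describes the two-state site model used to generate ground-truth-labeled
#' alignments: each site is independently in the divergent state F1 with
#' probability `theta_true`. An F0 (constrained) site draws one rate
#' `lambda ~ Gamma(alpha, beta)` shared by both gene clusters; an F1 site
#' draws independent rates for the two clusters from the same gamma.
#' Characters then evolve along each cluster tree by a Poisson substitution
#' process at the site's rate, each event replacing the current state by a
#' uniformly chosen different state.
#'
#' @param n_sites alignment length.
#' @param theta_true true fraction of divergent sites, in \[0, 1\].
#' @param tree1,tree2 ape `phylo` trees (branch lengths = expected
#'   substitutions/site at rate 1) for the two clusters; tip labels must be
#'   disjoint.
#' @param alpha,beta gamma shape and rate of the site-rate distribution
#'   (defaults 0.5/0.5: mean rate 1 with strong among-site heterogeneity,
#'   typical of protein data).
#' @param alphabet_size number of character states (default 20).
#' @param seed RNG seed.
#' @return object of class `evolution_spec`.
#' @export
evolution_spec <- function(n_sites, theta_true, tree1, tree2,
                           alpha = 0.5, beta = 0.5,
                           alphabet_size = 20L, seed = 1L) {
  n_sites <- check_count(n_sites, "n_sites")
  check_number(theta_true, "theta_true", lower = 0, upper = 1)
  check_number(alpha, "alpha", lower = 1e-12)
  check_number(beta, "beta", lower = 1e-12)
  alphabet_size <- check_count(alphabet_size, "alphabet_size", lower = 2L)
  for (tr in list(tree1, tree2)) {
    if (!inherits(tr, "phylo") || length(tr$tip.label) < 2L)
      stop_nd("each cluster tree must be a 'phylo' object with >= 2 tips")
    if (is.null(tr$edge.length) || any(tr$edge.length < 0))
      stop_nd("cluster trees need non-negative branch lengths")
  }
  if (length(intersect(tree1$tip.label, tree2$tip.label)) > 0L)
    stop_nd("cluster trees must have disjoint tip labels")
  structure(list(n_sites = n_sites, theta_true = theta_true,
                 tree1 = tree1, tree2 = tree2, alpha = alpha, beta = beta,
                 alphabet_size = alphabet_size, seed = as.integer(seed)),
            class = "evolution_spec")
}

# Evolve all sites down one tree. rates: per-site rate vector. Returns a
# taxa x sites character matrix. The end state of a branch carrying k
# Poisson events is drawn from the exact k-step uniform-replacement chain:
# P(same) = 1/A + (A-1)/A * (-1/(A-1))^k.
evolve_on_tree <- function(tree, rates, alphabet) {
  A <- length(alphabet)
  n_sites <- length(rates)
  tr <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- length(tr$tip.label)
  n_nodes <- n_tip + tr$Nnode
  states <- matrix(0L, n_nodes, n_sites)
  root <- n_tip + 1L
  states[root, ] <- sample.int(A, n_sites, replace = TRUE)
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    k <- rpois(n_sites, rates * tr$edge.length[e])
    p_same <- 1 / A + (A - 1) / A * (-1 / (A - 1))^k
    stay <- runif(n_sites) < p_same
    new_state <- states[parent, ]
    shift <- sample.int(A - 1L, n_sites, replace = TRUE)  # uniform other state
    moved <- ((states[parent, ] - 1L + shift) %% A) + 1L
    new_state[!stay] <- moved[!stay]
    states[child, ] <- new_state
  }
  out <- matrix(alphabet[states[seq_len(n_tip), ]], n_tip, n_sites)
  rownames(out) <- tr$tip.label
  out
}

#' Simulate a two-cluster alignment with known divergent sites
#'
#' Generates a labeled alignment under the two-state model of
#' [evolution_spec()]. Truth labels (site state and the rates actually
#' used) are returned alongside the characters, so downstream estimators
#' can be scored against ground truth.
#'
#' @param spec an [evolution_spec()].
#' @param site_state optional forced site labels (`"F0"`/`"F1"` vector of
#'   length `n_sites`) for constructing benchmark scenarios; by default
#'   states are drawn i.i.d. with `P(F1) = theta_true`.
#' @param rate1,rate2 optional per-site rate overrides (length `n_sites`,
#'   `NA` = draw from the model); used to plant sites with prescribed
#'   rates, e.g. the canonical type-I pattern of a site constrained in one
#'   cluster and relaxed in the other.
#' @return object of class `labeled_alignment`: `alignment` (taxa x sites
#'   character matrix), `cluster` (named membership vector, 1 or 2),
#'   `site_state`, `rate1`, `rate2`, and the `spec`.
#' @export
simulate_two_cluster_alignment <- function(spec, site_state = NULL,
                                           rate1 = NULL, rate2 = NULL) {
  stopifnot(inherits(spec, "evolution_spec"))
  if (!is.null(site_state)) {
    if (length(site_state) != spec$n_sites ||
        !all(site_state %in% c("F0", "F1")))
      stop_nd("'site_state' must be a vector of \"F0\"/\"F1\", one per site")
  }
  for (rt in list(rate1, rate2))
    if (!is.null(rt) && (length(rt) != spec$n_sites || any(rt < 0, na.rm = TRUE)))
      stop_nd("rate overrides must be non-negative, one value per site")
  alphabet <- if (spec$alphabet_size == 20L) AA_ALPHABET
              else AA_ALPHABET[seq_len(spec$alphabet_size)]
  res <- with_seed(spec$seed, {
    st <- site_state %||%
      ifelse(runif(spec$n_sites) < spec$theta_true, "F1", "F0")
    shared <- rgamma(spec$n_sites, shape = spec$alpha, rate = spec$beta)
    indep1 <- rgamma(spec$n_sites, shape = spec$alpha, rate = spec$beta)
    indep2 <- rgamma(spec$n_sites, shape = spec$alpha, rate = spec$beta)
    r1 <- ifelse(st == "F1", indep1, shared)
    r2 <- ifelse(st == "F1", indep2, shared)
    if (!is.null(rate1)) r1 <- ifelse(is.na(rate1), r1, rate1)
    if (!is.null(rate2)) r2 <- ifelse(is.na(rate2), r2, rate2)
    aln1 <- evolve_on_tree(spec$tree1, r1, alphabet)
    aln2 <- evolve_on_tree(spec$tree2, r2, alphabet)
    list(st = st, rate1 = r1, rate2 = r2, aln = rbind(aln1, aln2))
  })
  cluster <- setNames(c(rep(1L, length(spec$tree1$tip.label)),
                        rep(2L, length(spec$tree2$tip.label))),
                      rownames(res$aln))
  structure(list(alignment = res$aln, cluster = cluster,
                 site_state = res$st, rate1 = res$rate1, rate2 = res$rate2,
                 spec = spec),
            class = "labeled_alignment")
}

#' @export
print.labeled_alignment <- function(x, ...) {
  cat(sprintf("<labeled_alignment> %d taxa (%d + %d) x %d sites; %d F1 sites\n",
              nrow(x$alignment), sum(x$cluster == 1L), sum(x$cluster == 2L),
              ncol(x$alignment), sum(x$site_state == "F1")))
  invisible(x)
}

#' Write truth labels of a labeled alignment
#'
#' TSV with columns `site`, `state`, `rate1`, `rate2`.
#'
#' @param la a [simulate_two_cluster_alignment()] result.
#' @param path output file.
#' @export
write_truth_labels <- function(la, path) {
  stopifnot(inherits(la, "labeled_alignment"))
  df <- data.frame(site = seq_along(la$site_state), state = la$site_state,
                   rate1 = la$rate1, rate2 = la$rate2)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Balanced test tree
#'
#' A fully balanced rooted tree with equal branch lengths and numbered tip
#' labels, the reference shape for the synthetic evolution scenarios.
#'
#' @param n_tips number of tips (must be a power of 2).
#' @param branch_length every branch length (default 0.15
#'   substitutions/site, a typical within-cluster divergence).
#' @param prefix tip-label prefix.
#' @return an ape `phylo` tree.
#' @export
balanced_tree <- function(n_tips, branch_length = 0.15, prefix = "t") {
  tr <- ape::stree(n_tips, type = "balanced")
  tr$tip.label <- paste0(prefix, seq_len(n_tips))
  tr$edge.length <- rep(branch_length, nrow(tr$edge))
  tr
}
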