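toy_sup <- function(nf, n, seed = 1) {
  set.seed(seed)
  trajectory(array(rnorm(nf * n * 3), c(nf, n, 3)))
}

test_that("DCCM equals the direct definition, with unit diagonal and symmetry", {
  traj <- toy_sup(6, 4, seed = 9)
  d <- compute_dccm(traj)
  expect_equal(unclass(unname(d)), oracle_dccm(traj$coords),
               tolerance = 1e-12, ignore_attr = TRUE)
  for (s in 1:5) {
    di <- compute_dccm(toy_sup(5 + s, 3 + s, seed = s))
    expect_equal(diag(di), setNames(rep(1, 3 + s), rownames(di)))
    expect_equal(unclass(di), t(unclass(di)))
    expect_lte(max(abs(di)), 1 + 1e-12)
  }
})

test_that("exactly anti-correlated residues get C = -1", {
  set.seed(3)
  base <- matrix(rnorm(30), 10, 3)
  co <- array(0, c(10, 3, 3))
  co[, 1, ] <- base
  co[, 2, ] <- -base          # mirror motion
  co[, 3, ] <- matrix(rnorm(30), 10, 3)
  d <- compute_dccm(trajectory(co))
  expect_equal(unname(d[1, 2]), -1, tolerance = 1e-12)
})

test_that("a residue with zero fluctuation is reported by name", {
  co <- array(rnorm(60), c(5, 4, 3))
  co[, 2, ] <- matrix(rep(c(1, 2, 3), each = 5), 5, 3)  # frozen residue
  expect_error(compute_dccm(trajectory(co)), "ALA 2")
})

test_that("graph construction follows the -log|C| weight convention", {
  C <- diag(4)
  C[1, 2] <- C[2, 1] <- exp(-1)
  C[1, 3] <- C[3, 1] <- 0        # never an edge
  C[2, 4] <- C[4, 2] <- -0.9     # anti-correlation: edge via |C|
  rownames(C) <- colnames(C) <- paste("ALA", 1:4)
  g <- build_graph(C, 0.3)
  e12 <- g$edges[g$edges$i == "ALA 1" & g$edges$j == "ALA 2", ]
  expect_equal(e12$weight, 1.0, tolerance = 1e-12)
  expect_false(any(g$edges$i == "ALA 1" & g$edges$j == "ALA 3"))
  expect_true(any(g$edges$i == "ALA 2" & g$edges$j == "ALA 4"))
  expect_equal(g$edges$weight[g$edges$cor < 0], -log(0.9), tolerance = 1e-12)
  expect_equal(sum(g$adjacency), 2 * nrow(g$edges))
  expect_error(build_graph(C, 0), "0, 1")
  expect_error(build_graph(C, 1), "0, 1")
  # |C| = 1 -> weight 0
  C1 <- diag(3); C1[1, 2] <- C1[2, 1] <- 1 - 1e-15
  expect_equal(build_graph(C1, 0.5)$edges$weight, 0, tolerance = 1e-12)
})

path3_graph <- function() {
  C <- diag(3)
  C[1, 2] <- C[2, 1] <- exp(-1)
  C[2, 3] <- C[3, 2] <- exp(-1)
  rownames(C) <- colnames(C) <- as.character(1:3)
  build_graph(C, 0.3)
}

test_that("closeness and betweenness match hand-computed path graphs", {
  g <- path3_graph()
  expect_equal(unname(closeness_centrality(g)), c(2/3, 1, 2/3))
  expect_equal(unname(betweenness_centrality(g)), c(0, 1/3, 0))
  # complete graph, unit weights: closeness 1 everywhere, betweenness 0
  n <- 5
  C <- matrix(exp(-1), n, n); diag(C) <- 1
  rownames(C) <- colnames(C) <- as.character(1:n)
  gk <- build_graph(C, 0.3)
  expect_equal(unname(closeness_centrality(gk)), rep(1, n))
  expect_equal(unname(betweenness_centrality(gk)), rep(0, n))
  expect_equal(unname(degree_centrality(gk)), rep(n - 1L, n))
  # 4-node star: center betweenness 3/6
  Cs <- diag(4); Cs[1, 2:4] <- Cs[2:4, 1] <- exp(-1)
  rownames(Cs) <- colnames(Cs) <- as.character(1:4)
  gs <- build_graph(Cs, 0.3)
  expect_equal(unname(betweenness_centrality(gs)), c(0.5, 0, 0, 0))
})

test_that("centralities agree with the exhaustive-path oracle on random graphs", {
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(4:8, 1)
    C <- random_graph_dccm(n, p_edge = runif(1, 0.3, 0.8))
    g <- build_graph(C, 0.3)
    oc <- oracle_centralities(weight_matrix(g))
    expect_equal(unname(closeness_centrality(g)), oc$closeness,
                 tolerance = 1e-10)
    expect_equal(unname(betweenness_centrality(g)), oc$betweenness,
                 tolerance = 1e-10)
    expect_equal(unname(degree_centrality(g)), oc$degree)
  }
})

test_that("raising the cutoff never increases any degree", {
  set.seed(5)
  C <- random_graph_dccm(10, p_edge = 0.7, cutoff = 0.05, cmax = 0.99)
  cuts <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  degs <- sapply(cuts, function(ct) degree_centrality(build_graph(C, ct)))
  for (k in 2:length(cuts)) expect_true(all(degs[, k] <= degs[, k - 1]))
})

test_that("permuting residues permutes the DCCM and centralities consistently", {
  traj <- toy_sup(8, 5, seed = 6)
  perm <- c(3, 1, 5, 2, 4)
  traj_p <- trajectory(traj$coords[, perm, , drop = FALSE])
  d <- compute_dccm(traj); dp <- compute_dccm(traj_p)
  expect_equal(unname(unclass(dp)), unname(unclass(d))[perm, perm],
               tolerance = 1e-12, ignore_attr = TRUE)
  g <- build_graph(unname(unclass(d)), 0.2)
  gp <- build_graph(unname(unclass(dp)), 0.2)
  expect_equal(unname(degree_centrality(gp)),
               unname(degree_centrality(g))[perm])
})

test_that("rank_top orders by value with residue-number tie-breaks", {
  tab <- data.frame(node = c("ALA 10", "GLY 2", "LYS 7"),
                    betweenness = c(0.2, 0.2, 0.5),
                    closeness = c(1, 1, 1), degree = c(3L, 2L, 1L))
  class(tab) <- c("centrality_table", "data.frame")
  top <- rank_top(tab, k = 2)
  expect_equal(top$betweenness, c("LYS 7", "GLY 2"))  # tie: lower resno first
  expect_equal(top$closeness, c("GLY 2", "LYS 7"))
  expect_equal(rank_top(tab, k = 10)$degree,
               c("ALA 10", "GLY 2", "LYS 7"))  # k > n returns all
  # planted hub ranks first everywhere
  C <- hub_correlation(12, hubs = 4, rho = 0.65)
  tr <- simulate_trajectory(trajectory_spec(12, 1500, C, seed = 2))
  ct <- centrality_table(build_graph(compute_dccm(tr), 0.5))
  top1 <- rank_top(ct, 1)
  expect_equal(top1$betweenness, "ALA 4")
  expect_equal(top1$closeness, "ALA 4")
  expect_equal(top1$degree, "ALA 4")
  expect_equal(top1$overlap, "ALA 4")
})
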