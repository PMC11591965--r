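test_that("p-distance counts differing sites with pairwise deletion", {
  aln <- rbind(a = c("A", "C", "D", "E"),
               b = c("A", "C", "D", "F"),
               c = c("A", "-", "D", "E"),
               d = c("A", "C", "D", "F"))
  expect_equal(p_distance(aln, "a", "a"), 0)
  expect_equal(p_distance(aln, "a", "b"), 0.25)
  expect_equal(p_distance(aln, "c", "d"), 1 / 3)  # gap column dropped
  expect_equal(p_distance(aln, "a", "b"), p_distance(aln, "b", "a"))
  d <- p_distance_matrix(aln)
  expect_equal(d, t(d))
  expect_equal(diag(d), setNames(rep(0, 4), rownames(aln)))
  gap <- rbind(x = c("-", "-"), y = c("A", "C"))
  expect_error(p_distance(gap, "x", "y"), "comparable")
})

test_that("neighbor joining reproduces closed-form small cases", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("a", "b"),
                                                        c("a", "b")))
  t2 <- neighbor_joining(d2)
  expect_equal(sum(t2$edge.length), 0.4)
  expect_equal(ape::cophenetic.phylo(t2)["a", "b"], 0.4)

  taxa <- c("a", "b", "c")
  d3 <- matrix(0, 3, 3, dimnames = list(taxa, taxa))
  d3["a", "b"] <- d3["b", "a"] <- 0.6
  d3["a", "c"] <- d3["c", "a"] <- 0.8
  d3["b", "c"] <- d3["c", "b"] <- 0.9
  t3 <- neighbor_joining(d3)
  co <- ape::cophenetic.phylo(t3)
  # three-point formulas: b_a = (d_ab + d_ac - d_bc)/2 etc.
  expect_equal(co["a", "b"], 0.6, tolerance = 1e-12)
  expect_equal(co["a", "c"], 0.8, tolerance = 1e-12)
  expect_equal(co["b", "c"], 0.9, tolerance = 1e-12)
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("neighbor joining recovers additive matrices exactly", {
  set.seed(10)
  for (rep in 1:30) {
    n <- sample(4:8, 1)
    at <- random_additive_tree(n)
    tr <- neighbor_joining(at$d)
    co <- ape::cophenetic.phylo(tr)
    co <- co[rownames(at$d), colnames(at$d)]
    expect_lt(max(abs(co - at$d)), 1e-10)
    # independent cross-check of the topology against ape's NJ
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr),
                                           ape::unroot(ape::nj(at$d)))), 0)
  }
})

test_that("negative NJ branch estimates are clamped without changing path sums", {
  # a noisy (non-additive) matrix known to produce a negative NJ estimate
  taxa <- letters[1:4]
  d <- matrix(c(0, 0.30, 0.45, 0.45,
                0.30, 0, 0.45, 0.45,
                0.45, 0.45, 0, 0.05,
                0.45, 0.45, 0.05, 0), 4, 4, dimnames = list(taxa, taxa))
  tr <- neighbor_joining(d)
  expect_true(all(tr$edge.length >= 0))
})

test_that("Fitch counts match the worked examples", {
  star <- ape::stree(4, "star")
  star$tip.label <- letters[1:4]
  star$edge.length <- rep(1, 4)
  aln <- rbind(a = c("A", "A", "A"),
               b = c("A", "C", "C"),
               c = c("A", "G", "A"),
               d = c("A", "T", "C"))
  got <- fitch_site_changes(aln, star, alphabet = c("A", "C", "G", "T"))
  expect_equal(got, c(0L, 3L, 1L))  # invariant, all-distinct (k-1), one change

  bal <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  aln2 <- rbind(a = "A", b = "A", c = "C", d = "C")
  expect_equal(fitch_site_changes(aln2, bal, alphabet = c("A", "C")), 1L)

  # gaps are missing data: a gapped leaf can take any state for free
  aln3 <- rbind(a = "A", b = "-", c = "C", d = "C")
  expect_equal(fitch_site_changes(aln3, bal, alphabet = AA_ALPHABET), 1L)
  expect_error(fitch_site_changes(aln2, bal, cluster_taxa = "a"), "2 taxa")
})

test_that("Fitch equals brute-force minimization over internal labelings", {
  set.seed(21)
  alphabet <- c("A", "C", "G", "T")
  for (rep in 1:30) {
    k <- sample(3:6, 1)
    tr <- ape::rtree(k, br = NULL)
    tr$edge.length <- rep(1, nrow(tr$edge))
    states <- sample(c(alphabet, "-"), k, replace = TRUE,
                     prob = c(rep(0.22, 4), 0.12))
    aln <- matrix(states, ncol = 1, dimnames = list(tr$tip.label, NULL))
    got <- fitch_site_changes(aln, tr, alphabet = alphabet)
    want <- oracle_fitch(tr, setNames(states, tr$tip.label), alphabet)
    expect_equal(got, as.integer(want))
  }
})

test_that("Fitch counts agree with phangorn on amino-acid data", {
  skip_if_not_installed("phangorn")
  t1 <- balanced_tree(8, 0.1)
  la <- simulate_two_cluster_alignment(
    evolution_spec(200, 0.5, t1, balanced_tree(8, 0.1, "b"), seed = 2))
  pd <- phangorn::phyDat(la$alignment[t1$tip.label, ], type = "AA")
  ph <- phangorn::fitch(t1, pd, site = "site")
  expect_equal(fitch_site_changes(la$alignment, t1),
               as.integer(ph[attr(pd, "index")]))
})

test_that("tree length sums all branch lengths", {
  tr <- balanced_tree(8, 0.15)
  expect_equal(tree_length(tr), 14 * 0.15)
  expect_error(tree_length(ape::rtree(4, br = NULL)), "branch lengths")
})
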