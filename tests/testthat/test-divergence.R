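test_that("marginal count distribution matches closed form, quadrature and sums to 1", {
  expect_equal(marginal_Q(0, 1, 1, 1), 0.5, tolerance = 1e-12)
  expect_equal(sum(marginal_Q(0:500, 1.3, 0.8, 2.5)), 1, tolerance = 1e-10)
  # negative-binomial identity (independent implementation in stats)
  i <- 0:20
  expect_equal(marginal_Q(i, 2.2, 1.7, 3),
               dnbinom(i, size = 2.2, prob = 1.7 / (1.7 + 3)),
               tolerance = 1e-12)
  set.seed(8)
  for (rep in 1:10) {
    a <- runif(1, 0.3, 5); b <- runif(1, 0.3, 5); T <- runif(1, 0.5, 8)
    k <- sample(0:6, 1)
    expect_equal(marginal_Q(k, a, b, T), oracle_Q_quad(k, a, b, T),
                 tolerance = 1e-8)
  }
})

test_that("shared-rate joint matches quadrature and sums to 1", {
  expect_equal(joint_K12(0, 0, 1, 1, 1, 1), 1 / 3, tolerance = 1e-12)
  grid <- expand.grid(i = 0:60, j = 0:60)
  expect_equal(sum(joint_K12(grid$i, grid$j, 1.5, 1.2, 0.8, 1.1)), 1,
               tolerance = 1e-8)
  set.seed(9)
  for (rep in 1:10) {
    a <- runif(1, 0.3, 4); b <- runif(1, 0.3, 4)
    T1 <- runif(1, 0.5, 5); T2 <- runif(1, 0.5, 5)
    i <- sample(0:5, 1); j <- sample(0:5, 1)
    expect_equal(joint_K12(i, j, a, b, T1, T2),
                 oracle_K12_quad(i, j, a, b, T1, T2), tolerance = 1e-8)
  }
})

test_that("gamma fit recovers simulated shape and is T-invariant", {
  set.seed(12)
  lam <- rgamma(1e5, shape = 2, rate = 1)
  x <- rpois(1e5, lam * 5)
  fit <- fit_gamma(x, 5)
  expect_equal(fit$alpha, 2, tolerance = 0.1)
  expect_equal(fit$beta, 1, tolerance = 0.1)
  # scaling T: same rates observed over a longer time
  x2 <- rpois(1e5, lam * 15)
  fit2 <- fit_gamma(x2, 15)
  expect_equal(fit2$alpha, fit$alpha, tolerance = 0.15)
  expect_equal(fit2$beta, fit$beta, tolerance = 0.15)
  # underdispersed counts: corrected variance collapses
  expect_error(fit_gamma(rep(2L, 100), 1), "heterogeneity")
  expect_error(fit_gamma(rep(c(1L, 2L), 50), 1), "heterogeneity")
})

test_that("perfectly correlated counts give r = 1, theta = 0", {
  set.seed(13)
  lam <- rgamma(500, 0.5, 0.5)
  X <- rpois(500, lam * 4)
  est <- estimate_theta(X, X, 4, 4, n_boot = 0)
  # identical counts: the Poisson correction makes r_lambda exceed 1
  # (Cov(X,X) = Var(X) is uncorrected); theta clips to exactly 0
  expect_gte(est$r_lambda, 1)
  expect_equal(est$theta, 0)
  expect_error(estimate_theta(X[1:5], X[1:5], 4, 4), "10 sites")
})

test_that("theta moment estimator recovers independent-rate simulations", {
  set.seed(14)
  n <- 2000; T1 <- 3; T2 <- 4
  l1 <- rgamma(n, 0.5, 0.5); l2 <- rgamma(n, 0.5, 0.5)
  est <- estimate_theta(rpois(n, l1 * T1), rpois(n, l2 * T2), T1, T2,
                        n_boot = 50, seed = 1)
  expect_equal(est$theta, 1, tolerance = 0.1)
  expect_true(is.finite(est$theta_se))
  # theta_true = 0.3 mixture, Poisson counts: mean recovery over replicates
  th_hat <- sapply(1:20, function(r) {
    set.seed(100 + r)
    st <- runif(n) < 0.3
    shared <- rgamma(n, 0.5, 0.5)
    l1 <- ifelse(st, rgamma(n, 0.5, 0.5), shared)
    l2 <- ifelse(st, rgamma(n, 0.5, 0.5), shared)
    estimate_theta(rpois(n, l1 * T1), rpois(n, l2 * T2), T1, T2,
                   n_boot = 0)$theta
  })
  expect_equal(mean(th_hat), 0.3, tolerance = 0.05)
})

test_that("bootstrap SE is reproducible under a seed", {
  set.seed(15)
  lam <- rgamma(300, 1, 1)
  X1 <- rpois(300, lam * 3); X2 <- rpois(300, lam * 3)
  e1 <- estimate_theta(X1, X2, 3, 3, n_boot = 100, seed = 7)
  e2 <- estimate_theta(X1, X2, 3, 3, n_boot = 100, seed = 7)
  expect_identical(e1$theta_se, e2$theta_se)
})

test_that("posterior limits and monotonicity in theta", {
  X1 <- c(0, 1, 5, 2); X2 <- c(4, 1, 0, 2)
  expect_equal(site_posterior(X1, X2, 0, 1, 1, 2, 2), rep(0, 4))
  expect_equal(site_posterior(X1, X2, 1, 1, 1, 2, 2), rep(1, 4))
  thetas <- seq(0, 1, by = 0.05)
  post <- sapply(thetas, function(th) site_posterior(X1, X2, th, 1, 1, 2, 2))
  for (s in 1:4) expect_true(all(diff(post[s, ]) >= -1e-12))
  expect_true(all(post >= 0 & post <= 1))
})

test_that("true-F1 sites score higher posteriors than true-F0 sites", {
  t1 <- balanced_tree(8, 0.1, "a"); t2 <- balanced_tree(8, 0.1, "b")
  la <- simulate_two_cluster_alignment(
    evolution_spec(2000, 0.5, t1, t2, seed = 31))
  X1 <- fitch_site_changes(la$alignment, t1)
  X2 <- fitch_site_changes(la$alignment, t2)
  div <- functional_divergence(X1, X2, tree_length(t1), tree_length(t2),
                               n_boot = 0)
  f1 <- la$site_state == "F1"
  expect_gt(mean(div$posterior[f1]), mean(div$posterior[!f1]))
  # top decile of posterior-ranked sites is F1-enriched beyond the prior
  top <- order(div$posterior, decreasing = TRUE)[1:200]
  expect_gt(mean(f1[top]), mean(f1))
})
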