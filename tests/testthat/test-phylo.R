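test_that("newick reading validates and round-trips the cophenetic matrix", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1);", path)
  tr <- read_newick(path)
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(cophenetic_distances(tr)["A", "B"], 2)
  tr2 <- simulate_tree(9, seed = 2)
  path2 <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr2, path2)
  labs <- tr2$tip.label
  expect_equal(cophenetic_distances(read_newick(path2))[labs, labs],
               cophenetic_distances(tr2), tolerance = 1e-8)
  bad <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B", bad)
  expect_error(read_newick(bad))
  nolen <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A,B);", nolen)
  expect_error(read_newick(nolen), "branch lengths")
})

test_that("patristic distances equal brute-force path sums on a caterpillar tree", {
  cat_tree <- ape::read.tree(text = "(((A:1,B:2):3,C:4):5,D:6);")
  d <- cophenetic_distances(cat_tree)
  for (a in cat_tree$tip.label) {
    for (b in cat_tree$tip.label) {
      if (a == b) next
      expect_equal(d[a, b], path_distance(cat_tree, a, b))
    }
  }
  # ultrametric: three-point condition and equal root-tip depths
  tru <- simulate_tree(10, seed = 6)
  du <- cophenetic_distances(tru)
  tips <- tru$tip.label
  set.seed(1)
  for (i in 1:30) {
    abc <- sample(tips, 3)
    two_largest <- sort(c(du[abc[1], abc[2]], du[abc[1], abc[3]], du[abc[2], abc[3]]),
                        decreasing = TRUE)[1:2]
    expect_equal(two_largest[1], two_largest[2], tolerance = 1e-9)
  }
})

test_that("BM covariance has the right structure and stays PSD", {
  cherry <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(unname(bm_covariance(cherry)), diag(2)) # no shared stem
  tr <- simulate_tree(7, seed = 3)
  v0 <- bm_covariance(tr, lambda_scale = 0)
  expect_true(all(v0[lower.tri(v0)] == 0))
  expect_equal(unname(diag(v0)), rep(1, 7)) # unit-height tree depths
  # d_ij = depth_i + depth_j - 2 V_ij on ultrametric trees
  v <- bm_covariance(tr)
  d <- cophenetic_distances(tr)
  expect_equal(d, outer(diag(v), diag(v), `+`) - 2 * v, tolerance = 1e-9)
  for (s in 1:50) {
    vv <- bm_covariance(simulate_tree(sample(4:12, 1), seed = 100 + s))
    expect_gt(min(eigen(vv, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  }
})

test_that("Blomberg K and Pagel lambda agree with an independent implementation", {
  skip_if_not_installed("phytools")
  tr <- simulate_tree(24, seed = 9)
  x <- simulate_trait_bm(tr, 0.7, 2, seed = 11)
  expect_equal(tidy(blomberg_k(tr, x, n_perm = 0))$estimate,
               as.numeric(phytools::phylosig(tr, x, method = "K")),
               tolerance = 1e-6)
  mine <- tidy(pagel_lambda(tr, x))
  ref <- phytools::phylosig(tr, x, method = "lambda")
  expect_equal(mine$estimate, ref$lambda, tolerance = 1e-4)
  expect_equal(mine$loglik, ref$logL, tolerance = 1e-6)
})

test_that("K is near 1 for Brownian traits and its permutation test holds size", {
  ks <- vapply(1:200, function(i) {
    tr <- simulate_tree(32, seed = 40000 + i)
    x <- simulate_trait_bm(tr, 1, 1, seed = 50000 + i)
    tidy(blomberg_k(tr, x, n_perm = 0))$estimate
  }, numeric(1))
  expect_gt(mean(ks), 0.85)
  expect_lt(mean(ks), 1.15)
  # size under shuffled (signal-free) traits
  tr <- simulate_tree(24, seed = 77)
  rej <- vapply(1:400, function(i) {
    x <- setNames(rnorm(24), tr$tip.label)
    blomberg_k(tr, x, n_perm = 99, seed = i)$p_value <= 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.03)
  expect_error(blomberg_k(tr, setNames(rep(1, 24), tr$tip.label)), "constant")
})

test_that("lambda ML sits at an optimum and detects boundary cases", {
  tr <- simulate_tree(40, seed = 5)
  x1 <- simulate_trait_bm(tr, 1, 1, seed = 6)
  fit <- pagel_lambda(tr, x1)
  v1 <- bm_covariance(tr, 1)
  ll_at <- function(lam, x) {
    v <- v1 * lam
    diag(v) <- diag(v1)
    phyllonet:::bm_profile_loglik(x, v)$loglik
  }
  expect_gte(fit$loglik + 1e-6, ll_at(0, x1))
  expect_gte(fit$loglik + 1e-6, ll_at(1, x1))
  expect_gte(fit$lr_statistic, 0)
  x0 <- setNames(rnorm(40), tr$tip.label)
  fit0 <- pagel_lambda(tr, x0)
  expect_lte(fit0$estimate, 0.3)
  if (fit0$lr_statistic <= 1e-8) expect_equal(fit0$p_value, 1)
})
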