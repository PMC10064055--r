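test_that("Hellinger transform is sqrt of relative abundance with unit row norms", {
  tab <- make_table(matrix(c(4L, 1L, 0L, 1L), 2, 2))
  h <- hellinger(tab)
  expect_equal(unname(h[1, ]), c(1, 0))
  expect_equal(unname(h[2, ]), rep(sqrt(0.5), 2))
  set.seed(2)
  big <- make_table(matrix(rpois(60, 5) + 1L, 6, 10))
  expect_equal(unname(rowSums(hellinger(big)^2)), rep(1, 6))
  zero <- make_table(rbind(matrix(1L, 1, 3), matrix(0L, 1, 3)))
  expect_error(hellinger(zero), "s2")
})

test_that("Bray-Curtis matches hand arithmetic and stays in [0, 1]", {
  m <- rbind(x = c(2, 1), y = c(1, 1), z = c(0, 3))
  colnames(m) <- c("a", "b")
  d <- bray_curtis(m)
  expect_equal(d["x", "y"], 0.2) # (1+0)/(3+2)
  expect_equal(d["x", "x"], 0)
  disj <- rbind(p = c(1, 0), q = c(0, 1))
  expect_equal(bray_curtis(disj)["p", "q"], 1)
  set.seed(4)
  hb <- bray_curtis(hellinger(make_table(matrix(rpois(80, 4) + 1L, 8, 10))))
  expect_true(all(hb >= 0 & hb <= 1))
  # invariant to sample reordering
  perm <- sample(8)
  tabm <- matrix(rpois(80, 4) + 1L, 8, 10, dimnames = list(paste0("s", 1:8), paste0("o", 1:10)))
  expect_equal(bray_curtis(tabm)[perm, perm], bray_curtis(tabm[perm, ]))
  expect_error(bray_curtis(rbind(a = c(0, 0), b = c(0, 0), cc = c(1, 1))), "all-zero")
})

test_that("NMDS recovers embeddable configurations with near-zero stress", {
  set.seed(1)
  d <- labelled_dist(matrix(rnorm(20), 10, 2))
  o <- nmds(d, k = 2, seed = 5)
  expect_lt(o$stress, 1e-3)
  expect_equal(unname(colMeans(as.matrix(o$coordinates[, -1]))), c(0, 0),
               tolerance = 1e-8)
  d3 <- labelled_dist(matrix(rnorm(6), 3, 2))
  expect_lt(nmds(d3, k = 1, seed = 2)$stress, 1e-6)
  expect_error(nmds(d3, k = 2, seed = 1), "smaller than")
  # determinism under seed
  o2 <- nmds(d, k = 2, seed = 5)
  expect_equal(o2$stress, o$stress)
  expect_equal(o2$coordinates, o$coordinates)
})

test_that("ANOSIM separates tight clusters and is centred under the null", {
  two <- rbind(matrix(rnorm(10, 0, 0.01), 5, 2), matrix(rnorm(10, 10, 0.01), 5, 2))
  d <- labelled_dist(two)
  g <- setNames(rep(c("a", "b"), each = 5), rownames(d))
  fit <- anosim(d, g, n_perm = 199, seed = 1)
  expect_equal(fit$statistic, 1)
  expect_gte(fit$p_value, 1 / 200)
  rs <- vapply(1:500, function(s) {
    set.seed(s + 3000)
    d0 <- labelled_dist(matrix(rnorm(24), 12, 2))
    anosim(d0, setNames(sample(rep(c("a", "b"), each = 6)), rownames(d0)),
           n_perm = 49, seed = s)$statistic
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.02)
  expect_true(all(rs >= -1 & rs <= 1))
  expect_error(anosim(d, setNames(c("a", rep("b", 9)), rownames(d))), "fewer than 2")
})

test_that("Mantel r hits the exact extremes and agrees with vegan on tail=greater", {
  set.seed(9)
  d1 <- labelled_dist(matrix(rnorm(16), 8, 2))
  self <- mantel(d1, d1, tail = "greater", n_perm = 99, seed = 1)
  expect_equal(self$statistic, 1)
  anti <- max(d1) - d1
  diag(anti) <- 0
  expect_equal(mantel(d1, anti, tail = "less", n_perm = 99, seed = 1)$statistic, -1)
  d2 <- labelled_dist(matrix(rnorm(16), 8, 2), ids = rownames(d1))
  mine <- mantel(d1, d2, tail = "greater", n_perm = 999, seed = 3)
  ref <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 999)
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_error(
    mantel(d1, labelled_dist(matrix(rnorm(16), 8, 2), ids = paste0("x", 1:8))),
    "same ids"
  )
})

test_that("paired log t-test reproduces the published tail probability", {
  # t = 1.92 on df = 10 must give the one-tailed p reported for the
  # epiphyte-vs-endophyte richness contrast (p = 0.042)
  expect_equal(pt(1.92, df = 10, lower.tail = FALSE), 0.042, tolerance = 0.02)
  # build data that realises t = 1.92, df = 10 exactly and check the tail
  set.seed(8)
  base <- rnorm(11)
  diffs <- base - mean(base)
  diffs <- diffs / sd(diffs) # mean 0, sd 1
  target_t <- 1.92
  diffs <- diffs + target_t / sqrt(11) # mean shifts t to target
  a <- exp(diffs + 5)
  b <- rep(exp(5), 11)
  names(a) <- names(b) <- paste0("h", 1:11)
  fit <- paired_t_log(a, b, tail = "greater")
  expect_equal(fit$statistic, 1.92, tolerance = 1e-8)
  expect_equal(fit$df, 10)
  expect_equal(fit$p_value, pt(1.92, 10, lower.tail = FALSE))
  # two-sided doubles the upper tail for a positive t; contracts hold
  two <- paired_t_log(a, b, tail = "two-sided")
  expect_equal(two$p_value, 2 * fit$p_value)
  expect_error(paired_t_log(2 * b, b), "zero variance")
  same <- setNames(c(1, 2, 4), c("x", "y", "z"))
  expect_error(paired_t_log(same, same), "zero variance")
})

test_that("Mantel permutation test keeps its nominal size on independent matrices", {
  rej <- vapply(1:300, function(s) {
    set.seed(s)
    d1 <- labelled_dist(matrix(rnorm(24), 12, 2))
    d2 <- labelled_dist(matrix(rnorm(24), 12, 2), ids = rownames(d1))
    mantel(d1, d2, tail = "less", n_perm = 99, seed = s)$p_value <= 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.035)
})
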