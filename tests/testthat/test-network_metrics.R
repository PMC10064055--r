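test_that("H2' hits the closed-form extremes", {
  expect_equal(specialization_h2(interaction_matrix(diag(4) * 5)), 1)
  expect_equal(specialization_h2(interaction_matrix(outer(c(1, 2, 3), c(4, 5, 6)))), 0)
  expect_error(specialization_h2(interaction_matrix(matrix(1:3, 1))), "at least 2")
})

test_that("H2' equals the brute-force minimum-entropy oracle on small integer matrices", {
  set.seed(42)
  checked <- 0
  while (checked < 40) {
    nr <- sample(2:3, 1)
    nc <- sample(2:3, 1)
    m <- matrix(rmultinom(1, sample(5:12, 1), rep(1, nr * nc))[, 1], nr, nc)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    checked <- checked + 1
    W <- sum(m)
    h2 <- table_entropy(m)
    h2max <- table_entropy(outer(rowSums(m), colSums(m)))
    h2min <- min(vapply(enumerate_tables(rowSums(m), colSums(m)),
                        table_entropy, numeric(1)))
    expected <- if (h2max - h2min < 1e-12) 0 else {
      min(1, max(0, (h2max - h2) / (h2max - h2min)))
    }
    got <- specialization_h2(interaction_matrix(m))
    expect_equal(got, expected, tolerance = 1e-9)
    expect_true(got >= 0 && got <= 1)
  }
})

test_that("weighted connectance matches hand-computed effective-partner counts", {
  expect_equal(weighted_connectance(interaction_matrix(matrix(7, 1, 1))), 0.5)
  expect_equal(weighted_connectance(interaction_matrix(matrix(2, 3, 5))), 0.5)
  for (n in c(2, 4, 7)) {
    expect_equal(weighted_connectance(interaction_matrix(diag(n) * 3)), 1 / (2 * n))
  }
})

test_that("WNODF follows the decreasing-fill rule with its tie convention", {
  expect_equal(wnodf(interaction_matrix(matrix(c(3, 1, 2, 0), 2, 2))), 100)
  checker <- suppressWarnings(interaction_matrix(matrix(c(1, 0, 0, 1), 2, 2)))
  expect_equal(wnodf(checker), 0) # tied marginal totals contribute zero
  m <- random_interaction(6, 8, seed = 5)
  p <- sample(6)
  q <- sample(8)
  expect_equal(wnodf(interaction_matrix(unclass(m)[p, q])), wnodf(m))
  # where marginal-total and binary-fill orderings coincide (distinct fills,
  # no ties), the independent vegan implementation gives the same value
  hand <- matrix(c(3, 1, 2, 0), 2, 2)
  expect_equal(wnodf(interaction_matrix(hand)),
               unname(vegan::nestednodf(hand, order = TRUE,
                                        weighted = TRUE)$statistic["NODF"]))
  expect_equal(wnodf(simulate_network(6, 9, "nested", noise = 0, seed = 2)), 100)
})

test_that("modularity equals exhaustive partition search on tiny networks", {
  set.seed(7)
  checked <- 0
  while (checked < 25) {
    np <- sample(2:3, 1)
    nf <- sample(2:3, 1)
    w <- matrix(sample(0:5, np * nf, replace = TRUE), np, nf)
    if (any(rowSums(w) == 0) || any(colSums(w) == 0)) next
    checked <- checked + 1
    q_star <- max(vapply(set_partitions(np + nf), function(g) barber_q(w, g),
                         numeric(1)))
    q <- bipartite_modularity(w, n_restarts = 20, seed = 3)$Q
    expect_equal(q, q_star, tolerance = 1e-9)
  }
})

test_that("modularity closed forms: one module gives 0, equal blocks give 0.5", {
  flat <- interaction_matrix(matrix(3, 4, 5))
  fit <- bipartite_modularity(flat, n_restarts = 5, seed = 1)
  expect_equal(fit$Q, 0, tolerance = 1e-12)
  blocks <- matrix(0, 4, 6)
  blocks[1:2, 1:3] <- 2
  blocks[3:4, 4:6] <- 2
  fit2 <- bipartite_modularity(interaction_matrix(blocks), n_restarts = 8, seed = 1)
  expect_equal(fit2$Q, 0.5)
  expect_equal(fit2$n_modules, 2L)
  mods <- tidy(fit2)
  expect_equal(mods$module[mods$species == "plant1"], mods$module[mods$species == "fungus1"])
  # reproducible under seed
  expect_equal(bipartite_modularity(interaction_matrix(blocks), n_restarts = 8, seed = 1)$Q,
               fit2$Q)
})

test_that("all four metrics are invariant to permutation and weight scaling", {
  m <- simulate_network(7, 12, "modular", n_modules = 2, noise = 0.2,
                        total_weight = 1000, seed = 11)
  set.seed(2)
  p <- sample(7)
  q <- sample(12)
  perm <- interaction_matrix(unclass(m)[p, q])
  scaled <- interaction_matrix(unclass(m) * 3)
  metrics <- function(x, seed) {
    c(specialization_h2(x), weighted_connectance(x), wnodf(x),
      bipartite_modularity(x, n_restarts = 20, seed = seed)$Q)
  }
  base <- metrics(m, 4)
  expect_equal(metrics(scaled, 4), base, tolerance = 1e-9)
  expect_equal(metrics(perm, 4)[1:3], base[1:3], tolerance = 1e-9)
  expect_equal(metrics(perm, 8)[4], base[4], tolerance = 1e-6)
})

test_that("the synthetic structure dial orders the metrics as designed", {
  h2_of <- function(structure) {
    mean(vapply(1:12, function(s) {
      specialization_h2(simulate_network(8, 12, structure, noise = 0.15,
                                         total_weight = 1500, seed = s))
    }, numeric(1)))
  }
  expect_gt(h2_of("specialized"), h2_of("random"))
  wn_nested <- mean(vapply(1:12, function(s) {
    wnodf(simulate_network(8, 12, "nested", noise = 0.15, total_weight = 1500,
                           seed = s))
  }, numeric(1)))
  wn_random <- mean(vapply(1:12, function(s) {
    wnodf(simulate_network(8, 12, "random", total_weight = 1500, seed = s))
  }, numeric(1)))
  expect_gt(wn_nested, wn_random)
})
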