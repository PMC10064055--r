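test_that("simulated trees are ultrametric, unit-height, and seed-reproducible", {
  tr <- simulate_tree(11, seed = 4)
  expect_equal(length(tr$tip.label), 11L)
  depths <- ape::node.depth.edgelength(tr)[seq_len(11)]
  expect_lt(max(depths) - min(depths), 1e-9)
  expect_equal(max(depths), 1)
  expect_identical(
    ape::write.tree(simulate_tree(11, seed = 4)),
    ape::write.tree(tr)
  )
  cherry <- simulate_tree(2, seed = 1)
  d2 <- ape::node.depth.edgelength(cherry)[1:2]
  expect_equal(d2[1], d2[2])
  expect_error(simulate_tree(1, seed = 1), ">= 2")
})

test_that("trait simulator matches the analytic lambda-scaled BM covariance", {
  # lambda = 0: distinct tips are independent
  tr <- simulate_tree(6, seed = 2)
  reps <- vapply(seq_len(1500), function(s) {
    simulate_trait_bm(tr, lambda_sim = 0, sigma2 = 1, seed = s)
  }, numeric(6))
  cv <- cov(t(reps))
  off <- cv[lower.tri(cv)]
  expect_lt(max(abs(off)), 0.12) # MC noise around analytic 0
  expect_lt(max(abs(diag(cv) - 1)), 0.15)
  # lambda = 1 on a cherry with a long shared stem: correlation ~ shared depth
  cherry <- ape::read.tree(text = "(A:0.1,B:0.1):0;")
  cherry$root.edge <- NULL
  deep <- ape::read.tree(text = "((A:0.1,B:0.1):0.9,C:1.0);")
  reps2 <- vapply(seq_len(1500), function(s) {
    simulate_trait_bm(deep, lambda_sim = 1, sigma2 = 1, seed = 10000 + s)
  }, numeric(3))
  expect_lt(abs(cor(reps2["A", ], reps2["B", ]) - 0.9), 0.05)
  expect_error(simulate_trait_bm(deep, 1, sigma2 = 0, seed = 1), "positive")
})

test_that("paired community tables respect depth, sharing, and seed", {
  tr <- simulate_tree(8, seed = 3)
  tabs <- simulate_paired_communities(tr, n_otus = 50, shared_fraction = 0.2,
                                      depth = 2000, seed = 11)
  expect_equal(unname(rowSums(otu_counts(tabs$epi))), rep(2000, 8))
  expect_equal(unname(rowSums(otu_counts(tabs$endo))), rep(2000, 8))
  expect_equal(length(intersect(colnames(tabs$epi), colnames(tabs$endo))), 10L)
  none <- simulate_paired_communities(tr, n_otus = 40, shared_fraction = 0,
                                      depth = 1000, seed = 5)
  expect_equal(partition_otus(none$epi, none$endo)$n_shared, 0L)
  again <- simulate_paired_communities(tr, n_otus = 50, shared_fraction = 0.2,
                                       depth = 2000, seed = 11)
  expect_identical(otu_counts(again$epi), otu_counts(tabs$epi))
})

test_that("network generator hits the closed-form extremes at zero noise", {
  modular <- simulate_network(4, 6, "modular", n_modules = 2, noise = 0,
                              total_weight = 240, seed = 1)
  expect_equal(bipartite_modularity(modular, n_restarts = 8, seed = 2)$Q, 0.5)
  nested <- simulate_network(5, 8, "nested", noise = 0, seed = 1)
  expect_equal(wnodf(nested), 100)
  spec <- simulate_network(5, 5, "specialized", noise = 0, seed = 1)
  expect_equal(specialization_h2(spec), 1)
  rnd <- simulate_network(6, 9, "random", total_weight = 500, seed = 3)
  expect_equal(sum(rnd), 500)
  expect_identical(
    unclass(simulate_network(6, 9, "random", total_weight = 500, seed = 3)),
    unclass(rnd)
  )
})

test_that("noise degrades modular and nested structure in expectation", {
  q_at <- function(noise) {
    mean(vapply(1:40, function(s) {
      m <- simulate_network(6, 12, "modular", n_modules = 3, noise = noise,
                            total_weight = 1200, seed = s)
      bipartite_modularity(m, n_restarts = 4, seed = s)$Q
    }, numeric(1)))
  }
  w_at <- function(noise) {
    mean(vapply(1:40, function(s) {
      wnodf(simulate_network(6, 12, "nested", noise = noise,
                             total_weight = 1200, seed = 100 + s))
    }, numeric(1)))
  }
  expect_true(q_at(0) > q_at(0.2) && q_at(0.2) > q_at(0.5))
  expect_true(w_at(0) > w_at(0.3))
})
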