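#' Simulate a pure-birth host phylogeny
#'
#' Rooted ultrametric Yule (pure-birth) tree rescaled to unit height, so a
#' branch length of 1 spans root to tips and the lambda signal parameter of
#' the trait simulator reads directly as the off-diagonal covariance
#' fraction. Tips are labelled `host01`, `host02`, ...
#'
#' @param n_tips Number of host species (>= 2).
#' @param seed Integer seed; the same seed yields an identical tree.
#' @return A `phylo` tree.
#' @export
simulate_tree <- function(n_tips, seed = 1L) {
  check_scalar_int(n_tips, "n_tips", min = 2)
  check_scalar_int(seed, "seed")
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  depths <- ape::node.depth.edgelength(tree)
  height <- max(depths[seq_len(n_tips)])
  tree$edge.length <- tree$edge.length / height
  tree$tip.label <- sprintf("host%02d", seq_len(n_tips))
  tree
}

#' Simulate a trait under lambda-scaled Brownian motion
#'
#' Multivariate normal draw with covariance `sigma2 *
#' bm_covariance(tree, lambda_sim)`: at `lambda_sim = 1` the trait evolves
#' by Brownian motion along the tree, at `lambda_sim = 0` tip values are
#' independent. Used both to generate test traits for the signal statistics
#' and as the host-affinity engine of [simulate_paired_communities()].
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param lambda_sim Phylogenetic signal in `[0, 1]`.
#' @param sigma2 Brownian rate (> 0).
#' @param seed Integer seed.
#' @return Named numeric vector of tip values.
#' @export
simulate_trait_bm <- function(tree, lambda_sim = 1, sigma2 = 1, seed = 1L) {
  tree <- validate_phylogeny(tree)
  check_proportion(lambda_sim, "lambda_sim")
  if (!is.numeric(sigma2) || length(sigma2) != 1L || sigma2 <= 0) {
    abort("`sigma2` must be a single positive number")
  }
  check_scalar_int(seed, "seed")
  set.seed(seed)
  draw_trait_bm(tree, lambda_sim, sigma2)
}

# RNG-stream version (no set.seed) used inside larger simulations.
draw_trait_bm <- function(tree, lambda_sim, sigma2) {
  v <- bm_covariance(tree, lambda_sim) * sigma2
  n <- nrow(v)
  ch <- chol(v + diag(1e-12, n))
  x <- drop(crossprod(ch, rnorm(n)))
  names(x) <- tree$tip.label
  x
}

#' Simulate paired epiphyte/endophyte OTU tables over a host tree
#'
#' Emulates a two-compartment leaf mycobiome survey: every OTU carries a
#' host-affinity trait evolved on the host phylogeny
#' ([simulate_trait_bm()]) — with signal `signal_lambda` for the epiphyte
#' pool and signal `endo_lambda` (default 0, mirroring the empirical
#' surface/interior contrast) for the endophyte pool. Affinities map
#' through a softmax with temperature `concentration` to each host's OTU
#' composition, and reads are drawn multinomially at the given depth, so
#' every sample totals exactly `depth` reads. A `shared_fraction` of OTU
#' ids is common to the two tables; the rest are compartment-specific.
#'
#' @param tree Host phylogeny; one sample per tip in each compartment.
#' @param n_otus OTUs per compartment (default 120).
#' @param shared_fraction Fraction of each compartment's OTU ids shared
#'   with the other compartment (default 0.14, the shared share observed
#'   in paired leaf surveys).
#' @param signal_lambda Phylogenetic signal of epiphyte host affinities.
#' @param endo_lambda Signal of endophyte affinities (default 0).
#' @param depth Reads per sample (default 10000).
#' @param concentration Softmax temperature (> 0, default 6): low values
#'   give flat generalist compositions, high values peaked specialists.
#' @param seed Integer seed.
#' @return List with [otu_table]s `epi` and `endo`.
#' @export
simulate_paired_communities <- function(tree, n_otus = 120, shared_fraction = 0.14,
                                        signal_lambda = 1, endo_lambda = 0,
                                        depth = 10000, concentration = 6,
                                        seed = 1L) {
  tree <- validate_phylogeny(tree)
  check_scalar_int(n_otus, "n_otus", min = 2)
  check_proportion(shared_fraction, "shared_fraction")
  check_proportion(signal_lambda, "signal_lambda")
  check_proportion(endo_lambda, "endo_lambda")
  check_scalar_int(depth, "depth", min = 1)
  if (!is.numeric(concentration) || concentration <= 0) {
    abort("`concentration` must be positive")
  }
  check_scalar_int(seed, "seed")
  n_shared <- round(shared_fraction * n_otus)
  shared_ids <- if (n_shared > 0) sprintf("OTU_sh%04d", seq_len(n_shared)) else character(0)
  epi_ids <- c(shared_ids, sprintf("OTU_ep%04d", seq_len(n_otus - n_shared)))
  endo_ids <- c(shared_ids, sprintf("OTU_en%04d", seq_len(n_otus - n_shared)))
  set.seed(seed)
  one_table <- function(otu_ids, lambda_sim) {
    v <- bm_covariance(tree, lambda_sim)
    ch <- chol(v + diag(1e-12, nrow(v)))
    z <- matrix(rnorm(nrow(v) * length(otu_ids)), nrow(v))
    aff <- crossprod(ch, z) # hosts x otus
    scaled <- concentration * aff
    comp <- exp(scaled - apply(scaled, 1, max))
    comp <- comp / rowSums(comp)
    counts <- t(apply(comp, 1, function(p) rmultinom(1, depth, p)[, 1L]))
    dimnames(counts) <- list(tree$tip.label, otu_ids)
    otu_table(counts)
  }
  list(
    epi = one_table(epi_ids, signal_lambda),
    endo = one_table(endo_ids, endo_lambda)
  )
}

#' Simulate a weighted bipartite interaction matrix with known structure
#'
#' Generates plant-fungus weight matrices whose architecture is a dial for
#' testing the network metrics:
#' * `"random"`: Patefield draw from uniform(ish) positive marginals;
#' * `"modular"`: equal blocks on the diagonal of a plants x fungi grid;
#' * `"nested"`: a staircase support with strictly decreasing marginal
#'   totals and cell-wise decreasing weights (WNODF = 100 at zero noise);
#' * `"specialized"`: one-to-one near-diagonal interactions (H2' = 1 for a
#'   square matrix at zero noise).
#'
#' A `noise` fraction of the total weight is scattered uniformly over all
#' cells; the structured part is scaled by an integer factor towards
#' `total_weight` so zero-noise patterns keep their exact ties and
#' orderings.
#'
#' @param n_plants,n_fungi Dimensions.
#' @param structure `"random"`, `"modular"`, `"nested"` or `"specialized"`.
#' @param n_modules Number of modules for the modular structure.
#' @param noise Fraction of weight placed off-structure, in `[0, 1)`.
#' @param total_weight Approximate grand total of the matrix.
#' @param seed Integer seed.
#' @return An [interaction_matrix] with integer weights.
#' @export
simulate_network <- function(n_plants, n_fungi,
                             structure = c("random", "modular", "nested", "specialized"),
                             n_modules = 2, noise = 0, total_weight = 2000,
                             seed = 1L) {
  structure <- match.arg(structure)
  check_scalar_int(n_plants, "n_plants", min = 2)
  check_scalar_int(n_fungi, "n_fungi", min = 2)
  check_scalar_int(n_modules, "n_modules", min = 1)
  if (n_modules > min(n_plants, n_fungi)) {
    abort("`n_modules` must not exceed min(n_plants, n_fungi)")
  }
  check_proportion(noise, "noise")
  check_scalar_int(total_weight, "total_weight", min = 1)
  check_scalar_int(seed, "seed")
  set.seed(seed)
  base <- switch(structure,
    random = {
      r <- 1L + rmultinom(1, total_weight - n_plants, rep(1, n_plants))[, 1L]
      cc <- 1L + rmultinom(1, total_weight - n_fungi, rep(1, n_fungi))[, 1L]
      r2dtable(1, r, cc)[[1L]]
    },
    modular = {
      pm <- sort(rep(seq_len(n_modules), length.out = n_plants))
      fm <- sort(rep(seq_len(n_modules), length.out = n_fungi))
      outer(pm, fm, `==`) * 1L
    },
    nested = {
      b <- matrix(0L, n_plants, n_fungi)
      for (i in seq_len(n_plants)) {
        width <- ceiling(n_fungi * (n_plants - i + 1) / n_plants)
        j <- seq_len(width)
        b[i, j] <- (n_plants - i + 1L) * (n_fungi - j + 1L)
      }
      b
    },
    specialized = {
      b <- matrix(0L, n_plants, n_fungi)
      b[cbind(seq_len(n_plants), ((seq_len(n_plants) - 1L) %% n_fungi) + 1L)] <- 1L
      if (n_fungi > n_plants) {
        extra <- (n_plants + 1L):n_fungi
        b[cbind(((extra - 1L) %% n_plants) + 1L, extra)] <- 1L
      }
      b
    }
  )
  if (structure == "random") {
    w <- base
  } else {
    k <- max(1L, round((1 - noise) * total_weight / sum(base)))
    w <- base * k
    if (noise > 0) {
      n_noise <- round(sum(w) * noise / (1 - noise))
      if (n_noise > 0) {
        scatter <- rmultinom(1, n_noise, rep(1, length(w)))[, 1L]
        w <- w + matrix(scatter, nrow(w), ncol(w))
      }
    }
  }
  dimnames(w) <- list(
    sprintf("plant%02d", seq_len(n_plants)),
    sprintf("fungus%03d", seq_len(n_fungi))
  )
  suppressWarnings(interaction_matrix(w))
}
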