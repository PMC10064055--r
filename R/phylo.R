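#' Read a rooted phylogeny from a newick file
#'
#' Thin validating wrapper around [ape::read.tree()]: the tree must have at
#' least two uniquely labelled tips and a branch length on every edge
#' (polytomies are preserved). Used for the host-plant tree whose tip labels
#' match the sample identifiers of the OTU tables.
#'
#' @param path Path to a newick file.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(path)), # ape warns, then returns NULL
    error = function(e) abort(sprintf("failed to parse newick in '%s': %s", path, conditionMessage(e)))
  )
  if (is.null(tree)) abort(sprintf("failed to parse newick in '%s'", path))
  validate_phylogeny(tree)
}

validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) abort("expected a `phylo` tree")
  if (length(tree$tip.label) < 2L) abort("tree must have at least 2 tips")
  if (anyDuplicated(tree$tip.label)) abort("tip labels must be unique")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    abort("tree must have branch lengths on every edge")
  }
  if (any(tree$edge.length < 0)) abort("branch lengths must be nonnegative")
  tree
}

#' Patristic distances between tips
#'
#' Sums of branch lengths along the path between every pair of tips,
#' used as the host phylogenetic distance in the Mantel stage.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @return A labelled symmetric matrix with zero diagonal.
#' @export
cophenetic_distances <- function(tree) {
  tree <- validate_phylogeny(tree)
  d <- cophenetic(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Brownian-motion covariance of a tree, with Pagel lambda scaling
#'
#' Under Brownian trait evolution the covariance of two tips equals the
#' shared branch length from the root to their most recent common ancestor.
#' `lambda_scale` multiplies the off-diagonal entries only, interpolating
#' between a star phylogeny (0, independent tips) and the full Brownian
#' structure (1). This is the shared kernel behind [blomberg_k()] and
#' [pagel_lambda()].
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param lambda_scale Off-diagonal multiplier in `[0, 1]`.
#' @return A tips-by-tips covariance matrix in tip-label order.
#' @export
bm_covariance <- function(tree, lambda_scale = 1) {
  tree <- validate_phylogeny(tree)
  check_proportion(lambda_scale, "lambda_scale")
  v <- ape::vcv(tree)
  v <- v[tree$tip.label, tree$tip.label]
  d <- diag(v)
  v <- v * lambda_scale
  diag(v) <- d
  v
}

# Gaussian profile log-likelihood of a trait under covariance V, with the
# mean and the Brownian rate profiled out analytically (GLS mean, ML rate).
# Returns the log-likelihood plus the pieces reused by K and lambda.
bm_profile_loglik <- function(x, v) {
  n <- length(x)
  ch <- tryCatch(chol(v), error = function(e) NULL)
  if (is.null(ch)) abort("phylogenetic covariance matrix is singular")
  vi_x <- backsolve(ch, forwardsolve(t(ch), x))
  vi_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  one_vi_one <- sum(vi_1)
  a_hat <- sum(vi_x) / one_vi_one
  r <- x - a_hat
  vi_r <- vi_x - a_hat * vi_1
  mse_num <- sum(r * vi_r) # (x-a)' V^-1 (x-a)
  sigma2 <- mse_num / n
  logdet <- 2 * sum(log(diag(ch)))
  ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdet + n)
  list(
    loglik = ll, a_hat = a_hat, sigma2 = sigma2,
    mse_num = mse_num, ss0 = sum(r^2), one_vi_one = one_vi_one
  )
}

align_trait <- function(tree, trait) {
  trait <- as_trait_vector(trait)
  missing <- setdiff(tree$tip.label, names(trait))
  if (length(missing) > 0L) {
    abort(sprintf("trait missing for tip(s): %s", paste(missing, collapse = ", ")))
  }
  x <- trait[tree$tip.label]
  if (anyNA(x)) abort("trait contains NA values")
  if (var(x) == 0) abort("trait is constant across tips; signal is undefined")
  x
}

# K statistic alone (no permutations); v is bm_covariance(tree).
blomberg_k_stat <- function(x, v) {
  n <- length(x)
  prof <- bm_profile_loglik(x, v)
  obs_ratio <- prof$ss0 / prof$mse_num
  expected <- (sum(diag(v)) - n / prof$one_vi_one) / (n - 1)
  obs_ratio / expected
}

#' Blomberg's K phylogenetic signal with permutation test
#'
#' K compares the observed ratio of trait variance to phylogenetically
#' corrected variance against its Brownian-motion expectation on the same
#' tree; K near 1 matches Brownian evolution, K near 0 indicates no signal.
#' Significance is assessed by shuffling trait values across tips: the
#' p-value is the add-one-corrected proportion of permutations whose K is
#' at least the observed K.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param trait Named numeric vector (or two-column data frame) over tips.
#' @param n_perm Number of tip-label permutations (0 skips the test).
#' @param seed Integer seed for the permutations.
#' @return A `signal_result` with `estimate` (K), `p_value` and
#'   `n_permutations`; see [tidy.signal_result()].
#' @export
blomberg_k <- function(tree, trait, n_perm = 999, seed = 1L) {
  tree <- validate_phylogeny(tree)
  check_scalar_int(n_perm, "n_perm", min = 0)
  check_scalar_int(seed, "seed")
  x <- align_trait(tree, trait)
  v <- bm_covariance(tree)
  k_obs <- blomberg_k_stat(x, v)
  p <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    k_perm <- vapply(seq_len(n_perm), function(i) {
      blomberg_k_stat(sample(x), v)
    }, numeric(1))
    p <- (1 + sum(k_perm >= k_obs)) / (n_perm + 1)
  }
  new_signal_result(
    statistic_name = "K", estimate = k_obs, p_value = p,
    n_permutations = as.integer(n_perm)
  )
}

#' Pagel's lambda by maximum likelihood
#'
#' The lambda transformation multiplies the off-diagonal phylogenetic
#' covariances by lambda in `[0, 1]`; lambda = 0 is a star phylogeny (no
#' signal) and lambda = 1 full Brownian motion. The Gaussian likelihood is
#' profiled over the ancestral mean and Brownian rate and maximised over
#' lambda by bounded scalar optimisation; both interval endpoints are also
#' evaluated so a boundary optimum is never missed. Significance is a
#' likelihood-ratio test of lambda-hat against lambda = 0 on one degree of
#' freedom; a ratio of (numerically) zero gives p = 1.
#'
#' @inheritParams blomberg_k
#' @return A `signal_result` with `estimate` (lambda-hat), `p_value`,
#'   `loglik` at the optimum and `loglik_0` at lambda = 0.
#' @export
pagel_lambda <- function(tree, trait) {
  tree <- validate_phylogeny(tree)
  x <- align_trait(tree, trait)
  v1 <- bm_covariance(tree, 1)
  dv <- diag(diag(v1))
  ll_of <- function(lam) {
    v <- v1 * lam
    diag(v) <- diag(v1)
    bm_profile_loglik(x, v)$loglik
  }
  opt <- optimize(ll_of, interval = c(0, 1), maximum = TRUE, tol = 1e-8)
  cand <- c(opt$maximum, 0, 1)
  ll <- c(opt$objective, ll_of(0), ll_of(1))
  best <- which.max(ll)
  lam_hat <- cand[best]
  ll_hat <- ll[best]
  ll0 <- ll[2L]
  lr <- max(0, 2 * (ll_hat - ll0))
  p <- if (lr <= 1e-8) 1 else pchisq(lr, df = 1, lower.tail = FALSE)
  new_signal_result(
    statistic_name = "lambda", estimate = lam_hat, p_value = p,
    loglik = ll_hat, loglik_0 = ll0, lr_statistic = lr
  )
}

new_signal_result <- function(statistic_name, estimate, p_value,
                              n_permutations = NA_integer_,
                              loglik = NA_real_, loglik_0 = NA_real_,
                              lr_statistic = NA_real_) {
  structure(
    list(
      statistic_name = statistic_name, estimate = estimate, p_value = p_value,
      n_permutations = n_permutations, loglik = loglik, loglik_0 = loglik_0,
      lr_statistic = lr_statistic
    ),
    class = "signal_result"
  )
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf(
    "Phylogenetic signal %s = %.4g, p = %.4g\n",
    x$statistic_name, x$estimate, x$p_value
  ))
  invisible(x)
}

#' Tidy a phylogenetic-signal result
#'
#' @param x A `signal_result` from [blomberg_k()] or [pagel_lambda()].
#' @param ... Unused.
#' @return A one-row tibble.
#' @method tidy signal_result
#' @export
tidy.signal_result <- function(x, ...) {
  tibble(
    statistic_name = x$statistic_name, estimate = x$estimate,
    p_value = x$p_value, n_permutations = x$n_permutations,
    loglik = x$loglik, loglik_0 = x$loglik_0
  )
}

#' @method glance signal_result
#' @export
glance.signal_result <- function(x, ...) tidy(x)
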