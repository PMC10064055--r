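#' Construct a weighted bipartite interaction matrix
#'
#' Plants in rows, fungal OTUs in columns, nonnegative interaction weights
#' (read counts). Rows or columns that are entirely zero carry no
#' interaction and are dropped with a warning; the result always has a
#' positive grand total.
#'
#' @param w Nonnegative numeric matrix (or data frame with plant ids in the
#'   first column). Unnamed dimensions get default `plant*` / `fungus*` ids.
#' @return A validated matrix of class `interaction_matrix`.
#' @export
interaction_matrix <- function(w) {
  if (inherits(w, "interaction_matrix")) return(w)
  if (is.data.frame(w)) {
    ids <- as.character(w[[1L]])
    w <- as.matrix(w[, -1L, drop = FALSE])
    rownames(w) <- ids
  }
  w <- as.matrix(w)
  if (!is.numeric(w)) abort("weights must be numeric")
  if (anyNA(w) || any(w < 0)) abort("weights must be nonnegative and non-missing")
  if (is.null(rownames(w))) rownames(w) <- paste0("plant", seq_len(nrow(w)))
  if (is.null(colnames(w))) colnames(w) <- paste0("fungus", seq_len(ncol(w)))
  empty_r <- rowSums(w) == 0
  empty_c <- colSums(w) == 0
  if (any(empty_r) || any(empty_c)) {
    warn(sprintf(
      "dropping %d all-zero row(s) and %d all-zero column(s)",
      sum(empty_r), sum(empty_c)
    ))
    w <- w[!empty_r, !empty_c, drop = FALSE]
  }
  if (length(w) == 0L || sum(w) <= 0) abort("interaction matrix has no positive weight")
  structure(w, class = c("interaction_matrix", "matrix", "array"))
}

im_weights <- function(m) {
  m <- interaction_matrix(m)
  unclass(m)
}

#' Network-level specialization H2'
#'
#' The two-dimensional Shannon entropy `H2 = -sum(p_ij log p_ij)` of the
#' interaction frequencies `p_ij = w_ij / W` is rescaled between the
#' marginal-constrained extremes: `H2' = (H2max - H2) / (H2max - H2min)`.
#' `H2max` is the entropy of the independence table `r_i c_j / W` (the
#' maximum-entropy table with the observed marginals) and `H2min` the
#' minimum achievable entropy under the same marginals, found by greedily
#' packing each allocation into the cell that admits the largest single
#' transfer (the entropy minimum over the transportation polytope sits at a
#' vertex; the greedy visits vertices). H2' is 0 for perfectly generalised
#' networks and 1 for perfectly specialised ones.
#'
#' @param m An [interaction_matrix] with at least 2 rows and 2 columns.
#' @return A number in `[0, 1]`.
#' @export
specialization_h2 <- function(m) {
  w <- im_weights(m)
  if (nrow(w) < 2L || ncol(w) < 2L) abort("H2' needs at least 2 plants and 2 fungi")
  W <- sum(w)
  p <- w / W
  h2 <- shannon_entropy(p)
  r <- rowSums(w)
  cc <- colSums(w)
  h2max <- shannon_entropy(r) + shannon_entropy(cc) # entropy of outer product
  h2min <- h2min_entropy(r, cc)
  if (h2max - h2min <= .Machine$double.eps^0.5) {
    # all marginal mass in one row or one column: table is forced
    return(0)
  }
  min(1, max(0, (h2max - h2) / (h2max - h2min)))
}

# Minimum achievable entropy of a transportation table with the given
# marginals. The entropy is concave, so its minimum over the transportation
# polytope sits at a vertex; every vertex is reachable by repeatedly
# allocating the full min(row remainder, column remainder) to some cell
# (peel the forest support leaf by leaf). Small problems are solved exactly
# by branch-and-bound over those allocation sequences; larger ones fall
# back to the greedy packing heuristic (largest transfer first), whose
# discrepancy from the exact optimum is small and vanishes after the H2'
# normalisation on realistically sized networks.
h2min_entropy <- function(r, cc) {
  W <- sum(r)
  if (length(r) + length(cc) <= 9L) {
    h2min_exact(as.numeric(r), as.numeric(cc), W)
  } else {
    shannon_entropy(h2min_pack(r, cc) / W)
  }
}

h2min_exact <- function(r, cc, W) {
  best <- shannon_entropy(h2min_pack(r, cc) / W) # greedy upper bound
  memo <- new.env(parent = emptyenv())
  piece <- function(m) -(m / W) * log(m / W)
  dfs <- function(r_rem, c_rem, acc) {
    tot <- sum(r_rem)
    if (tot <= 1e-12) {
      if (acc < best) best <<- acc
      return(invisible())
    }
    # lower bound: all remaining weight in a single cell
    if (acc + piece(tot) >= best - 1e-12) return(invisible())
    key <- paste(c(sort(r_rem[r_rem > 0]), -1, sort(c_rem[c_rem > 0])), collapse = ",")
    prev <- memo[[key]]
    if (!is.null(prev) && prev <= acc + 1e-12) return(invisible())
    memo[[key]] <- acc
    rv <- unique(r_rem[r_rem > 0])
    cv <- unique(c_rem[c_rem > 0])
    for (a in rv) {
      for (b in cv) {
        m <- min(a, b)
        i <- which(r_rem == a)[1L]
        j <- which(c_rem == b)[1L]
        r2 <- r_rem
        c2 <- c_rem
        r2[i] <- r2[i] - m
        c2[j] <- c2[j] - m
        dfs(r2, c2, acc + piece(m))
      }
    }
  }
  dfs(r, cc, 0)
  best
}

# Greedy minimum-entropy packing of a transportation table with the given
# marginals: repeatedly place min(row remainder, column remainder) in the
# cell where that quantity is largest (ties: larger remainder sum, then
# lowest index). Each step exhausts a row or a column, so the support stays
# on a polytope vertex.
h2min_pack <- function(r, cc) {
  out <- matrix(0, length(r), length(cc))
  r_rem <- as.numeric(r)
  c_rem <- as.numeric(cc)
  while (sum(r_rem) > 1e-12) {
    cap <- outer(r_rem, c_rem, pmin)
    cap[r_rem <= 1e-12, ] <- -1
    cap[, c_rem <= 1e-12] <- -1
    best <- which(cap == max(cap))
    if (length(best) > 1L) {
      tot <- outer(r_rem, c_rem, `+`)
      best <- best[order(-tot[best], best)][1L]
    }
    i <- (best - 1L) %% length(r_rem) + 1L
    j <- (best - 1L) %/% length(r_rem) + 1L
    amt <- min(r_rem[i], c_rem[j])
    out[i, j] <- out[i, j] + amt
    r_rem[i] <- r_rem[i] - amt
    c_rem[j] <- c_rem[j] - amt
  }
  out
}

#' Weighted connectance
#'
#' Linkage density is the marginal-weighted mean number of effective
#' partners, `LD = (1/2W) * (sum_j c_j 2^(H_j) + sum_i r_i 2^(H_i))`, where
#' `H_i` is the base-2 Shannon entropy of row i's weights (so `2^(H_i)` is
#' row i's effective partner count) and `H_j` likewise for columns.
#' Weighted connectance divides LD by the total species number and lies in
#' (0, 0.5].
#'
#' @param m An [interaction_matrix].
#' @return A number in `(0, 0.5]`.
#' @export
weighted_connectance <- function(m) {
  w <- im_weights(m)
  W <- sum(w)
  eff_rows <- 2^apply(w, 1, shannon_entropy, base = 2)
  eff_cols <- 2^apply(w, 2, shannon_entropy, base = 2)
  ld <- (sum(colSums(w) * eff_cols) + sum(rowSums(w) * eff_rows)) / (2 * W)
  ld / (nrow(w) + ncol(w))
}

#' Weighted nestedness (WNODF)
#'
#' Nestedness metric based on Overlap and Decreasing Fill, weighted
#' version. Rows and columns are sorted by decreasing marginal totals; for
#' each ordered row pair (u above l) the paired term is 0 when the totals
#' are tied or increasing, and otherwise `100 * #\{j : 0 < w_lj < w_uj\} /
#' F_l` with `F_l` the number of nonzero cells in the lower row; column
#' pairs contribute symmetrically. WNODF is the average paired term over
#' all `n(n-1)/2 + m(m-1)/2` pairs, from 0 (no nested structure) to 100
#' (perfect nestedness).
#'
#' @param m An [interaction_matrix] with at least 2 rows and 2 columns.
#' @return A number in `[0, 100]`.
#' @export
wnodf <- function(m) {
  w <- im_weights(m)
  if (nrow(w) < 2L || ncol(w) < 2L) abort("WNODF needs at least 2 rows and 2 columns")
  score_pairs <- function(x) {
    # x: matrix whose rows are compared (already the axis of interest)
    tot <- rowSums(x)
    ord <- order(tot, decreasing = TRUE)
    x <- x[ord, , drop = FALSE]
    tot <- tot[ord]
    n <- nrow(x)
    s <- 0
    for (u in seq_len(n - 1L)) {
      for (l in (u + 1L):n) {
        if (tot[u] <= tot[l]) next
        fl <- sum(x[l, ] > 0)
        s <- s + 100 * sum(x[l, ] > 0 & x[l, ] < x[u, ]) / fl
      }
    }
    s
  }
  n <- nrow(w)
  mm <- ncol(w)
  (score_pairs(w) + score_pairs(t(w))) / (n * (n - 1) / 2 + mm * (mm - 1) / 2)
}

#' Weighted bipartite modularity (Barber's Q)
#'
#' Maximises `Q = (1/W) * sum_ij (w_ij - r_i c_j / W) * delta(g_i, g_j)`
#' over joint module assignments of plants and fungi, using label
#' propagation with agglomerative refinement: nodes repeatedly move to the
#' adjacent module with the largest modularity gain (ties broken by lowest
#' module index; a fresh module is opened when every move has negative
#' gain), whole-module merges with positive gain are then applied, and the
#' cycle repeats until stable. The best of `n_restarts` differently
#' initialised runs is returned.
#'
#' @param m An [interaction_matrix].
#' @param n_restarts Number of optimisation restarts (default 20).
#' @param seed Integer seed; the result is reproducible under it.
#' @return A `modularity_result`: list with `Q`, `modules` (tibble:
#'   `species`, `guild`, `module`), `n_modules`, `restarts_used`, `seed`.
#' @export
bipartite_modularity <- function(m, n_restarts = 20, seed = 1L) {
  w <- im_weights(m)
  check_scalar_int(n_restarts, "n_restarts", min = 1)
  check_scalar_int(seed, "seed")
  W <- sum(w)
  b <- w / W - outer(rowSums(w), colSums(w)) / W^2
  np <- nrow(b)
  nf <- ncol(b)
  set.seed(seed)
  best <- NULL
  for (rep in seq_len(n_restarts)) {
    gp <- if (rep == 1L) seq_len(np) else sample.int(max(2L, ceiling(np / 2)), np, replace = TRUE)
    res <- lp_optimize(b, gp)
    if (is.null(best) || res$q > best$q + 1e-12) best <- res
  }
  labs <- relabel_modules(c(best$gp, best$gf))
  structure(
    list(
      Q = best$q,
      modules = tibble(
        species = c(rownames(w), colnames(w)),
        guild = rep(c("plant", "fungus"), c(np, nf)),
        module = labs
      ),
      n_modules = length(unique(labs)),
      restarts_used = as.integer(n_restarts),
      seed = as.integer(seed)
    ),
    class = "modularity_result"
  )
}

relabel_modules <- function(g) {
  match(g, unique(g))
}

# One optimisation run: b is the (already normalised) modularity matrix,
# gp an initial plant labelling. Returns plant/fungus labels and Q.
lp_optimize <- function(b, gp) {
  np <- nrow(b)
  nf <- ncol(b)
  gf <- rep(0L, nf)
  q_of <- function(gp, gf) {
    k <- max(gp, gf)
    pm <- outer(gp, seq_len(k), `==`) * 1
    fm <- outer(gf, seq_len(k), `==`) * 1
    sum(diag(crossprod(pm, b %*% fm)))
  }
  repeat {
    # alternating local moves until stable
    repeat {
      changed <- FALSE
      k <- max(gp, if (any(gf > 0)) gf else 0L)
      pm <- matrix(0, np, k)
      pm[cbind(seq_len(np), gp)] <- 1
      gain_f <- crossprod(b, pm) # nf x k
      new_gf <- max.col(gain_f, ties.method = "first")
      best_gain <- gain_f[cbind(seq_len(nf), new_gf)]
      new_gf[best_gain < 0] <- k + seq_len(sum(best_gain < 0)) # fresh modules
      if (!identical(new_gf, gf)) {
        gf <- as.integer(new_gf)
        changed <- TRUE
      }
      k <- max(gp, gf)
      fm <- matrix(0, nf, k)
      fm[cbind(seq_len(nf), gf)] <- 1
      gain_p <- b %*% fm # np x k
      new_gp <- max.col(gain_p, ties.method = "first")
      best_gain <- gain_p[cbind(seq_len(np), new_gp)]
      new_gp[best_gain < 0] <- k + seq_len(sum(best_gain < 0))
      if (!identical(new_gp, gp)) {
        gp <- as.integer(new_gp)
        changed <- TRUE
      }
      g <- relabel_modules(c(gp, gf)) # compact labels jointly
      gp <- g[seq_len(np)]
      gf <- g[np + seq_len(nf)]
      if (!changed) break
    }
    # agglomerative refinement: merge module pairs with positive joint gain
    k <- max(gp, gf)
    if (k < 2L) break
    pm <- matrix(0, np, k)
    pm[cbind(seq_len(np), gp)] <- 1
    fm <- matrix(0, nf, k)
    fm[cbind(seq_len(nf), gf)] <- 1
    g2 <- crossprod(pm, b %*% fm) # k x k cross-module contributions
    merge_gain <- g2 + t(g2)
    diag(merge_gain) <- -Inf
    mg <- max(merge_gain)
    if (mg <= 1e-12) break
    idx <- which(merge_gain == mg, arr.ind = TRUE)[1L, ]
    s <- min(idx)
    t_ <- max(idx)
    gp[gp == t_] <- s
    gf[gf == t_] <- s
    g <- relabel_modules(c(gp, gf))
    gp <- g[seq_len(np)]
    gf <- g[np + seq_len(nf)]
  }
  list(gp = gp, gf = gf, q = q_of(gp, gf))
}

#' @export
print.modularity_result <- function(x, ...) {
  cat(sprintf(
    "Bipartite modularity Q = %.4f (%d modules, %d restarts)\n",
    x$Q, x$n_modules, x$restarts_used
  ))
  invisible(x)
}

#' @method tidy modularity_result
#' @export
tidy.modularity_result <- function(x, ...) x$modules

#' @method glance modularity_result
#' @export
glance.modularity_result <- function(x, ...) {
  tibble(Q = x$Q, n_modules = x$n_modules, restarts_used = x$restarts_used, seed = x$seed)
}

#' All four network-level metrics in one tibble
#'
#' @param m An [interaction_matrix].
#' @param n_restarts,seed Passed to [bipartite_modularity()].
#' @return A tibble with columns `metric` (`h2`, `modularity`,
#'   `connectance`, `wnodf`) and `value`.
#' @export
network_metrics <- function(m, n_restarts = 20, seed = 1L) {
  m <- interaction_matrix(m)
  tibble(
    metric = c("h2", "modularity", "connectance", "wnodf"),
    value = c(
      specialization_h2(m),
      bipartite_modularity(m, n_restarts = n_restarts, seed = seed)$Q,
      weighted_connectance(m),
      wnodf(m)
    )
  )
}
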