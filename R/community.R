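#' Hellinger transformation of a count table
#'
#' Square root of within-sample relative abundance: entry `sqrt(count /
#' sample total)`. Each transformed sample has unit sum of squares, which
#' downweights dominant OTUs before distance-based analyses.
#'
#' @param table An [otu_table] or numeric matrix with samples in rows.
#' @return A numeric matrix of the same shape.
#' @export
hellinger <- function(table) {
  m <- if (inherits(table, "otu_table")) otu_counts(table) else as.matrix(table)
  tot <- rowSums(m)
  if (any(tot == 0)) {
    abort(sprintf("sample '%s' has zero total reads", rownames(m)[which(tot == 0)[1L]]))
  }
  out <- vegan::decostand(m, method = "hellinger")
  out <- as.matrix(out)
  dimnames(out) <- dimnames(m)
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum(|x - y|) / sum(x + y)` between the abundance profiles of
#' every sample pair; 0 for identical profiles, 1 for disjoint supports.
#'
#' @param mat Nonnegative samples-by-OTUs matrix (often Hellinger-transformed).
#' @return A labelled symmetric distance matrix with zero diagonal.
#' @export
bray_curtis <- function(mat) {
  m <- if (inherits(mat, "otu_table")) otu_counts(mat) else as.matrix(mat)
  if (nrow(m) < 2L) abort("need at least 2 samples")
  if (any(m < 0)) abort("entries must be nonnegative")
  zero <- rowSums(m) == 0
  if (sum(zero) >= 2L) {
    abort(sprintf(
      "Bray-Curtis is undefined between all-zero samples: %s",
      paste(rownames(m)[zero], collapse = ", ")
    ))
  }
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  diag(d) <- 0
  d
}

as_distance_matrix <- function(d, arg = "dist") {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) abort(sprintf("`%s` must be square", arg))
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("e", seq_len(nrow(d)))
  }
  if (max(abs(d - t(d))) > 1e-12) abort(sprintf("`%s` must be symmetric", arg))
  if (any(abs(diag(d)) > 0)) abort(sprintf("`%s` must have a zero diagonal", arg))
  d
}

#' Nonmetric multidimensional scaling
#'
#' Ordination minimising Kruskal stress-1, the root mean squared mismatch
#' between configuration distances and monotone-regressed dissimilarities.
#' Runs [vegan::metaMDS()] on the dissimilarity matrix (multiple random
#' starts plus a metric-scaling start) and reports the lowest-stress
#' solution with centred coordinates.
#'
#' @param dist A symmetric dissimilarity matrix with zero diagonal.
#' @param k Number of ordination axes (default 2).
#' @param n_starts Maximum number of random starts (default 20).
#' @param max_iter Maximum iterations per start.
#' @param seed Integer seed; the result is reproducible under it.
#' @return An `ordination_result`: list with `coordinates` (tibble:
#'   `id`, `NMDS1`, ...), `stress`, `converged`, `n_starts_used`.
#' @export
nmds <- function(dist, k = 2, n_starts = 20, max_iter = 500, seed = 1L) {
  d <- as_distance_matrix(dist)
  check_scalar_int(k, "k", min = 1)
  if (k >= nrow(d) - 1L) {
    abort(sprintf("k = %d must be smaller than n - 1 = %d", k, nrow(d) - 1L))
  }
  set.seed(seed)
  fit <- suppressWarnings(suppressMessages(
    vegan::metaMDS(stats::as.dist(d), k = k, trymax = n_starts,
                   maxit = max_iter, trace = 0, autotransform = FALSE,
                   wascores = FALSE)
  ))
  pts <- sweep(fit$points, 2, colMeans(fit$points))
  colnames(pts) <- paste0("NMDS", seq_len(k))
  structure(
    list(
      coordinates = tibble(id = rownames(d), as_tibble(pts)),
      stress = fit$stress,
      converged = isTRUE(fit$converged > 0) || isTRUE(fit$converged),
      n_starts_used = fit$tries,
      seed = as.integer(seed)
    ),
    class = "ordination_result"
  )
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf(
    "NMDS ordination: stress-1 = %.4g (%s, %d starts)\n",
    x$stress, if (x$converged) "converged" else "not converged", x$n_starts_used
  ))
  invisible(x)
}

#' @method tidy ordination_result
#' @export
tidy.ordination_result <- function(x, ...) x$coordinates

#' @method glance ordination_result
#' @export
glance.ordination_result <- function(x, ...) {
  tibble(stress = x$stress, converged = x$converged, n_starts_used = x$n_starts_used)
}

#' @method autoplot ordination_result
#' @export
autoplot.ordination_result <- function(object, groups = NULL, ...) {
  df <- object$coordinates
  if (!is.null(groups)) df$group <- groups[df$id]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$NMDS1, .data$NMDS2)) +
    ggplot2::coord_equal() +
    ggplot2::labs(caption = sprintf("stress = %.3f", object$stress))
  if (is.null(groups)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
  }
}

new_perm_test <- function(method, statistic, p_value, n_permutations, tail,
                          seed = NA_integer_, df = NA_real_, permutations = NULL) {
  structure(
    list(
      method = method, statistic = statistic, p_value = p_value,
      n_permutations = n_permutations, tail = tail, seed = seed, df = df,
      permutations = permutations
    ),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "%s: statistic = %.4g, p = %.4g (tail = %s%s)\n",
    x$method, x$statistic, x$p_value, x$tail,
    if (!is.na(x$n_permutations)) sprintf(", %d permutations", x$n_permutations) else ""
  ))
  invisible(x)
}

#' Tidy a permutation/t test result
#'
#' @param x A `perm_test` from [anosim()], [mantel()] or [paired_t_log()].
#' @param ... Unused.
#' @return A one-row tibble with `method`, `statistic`, `p_value`,
#'   `n_permutations`, `tail`, `df`, `seed`.
#' @method tidy perm_test
#' @export
tidy.perm_test <- function(x, ...) {
  tibble(
    method = x$method, statistic = x$statistic, p_value = x$p_value,
    n_permutations = x$n_permutations, tail = x$tail, df = x$df, seed = x$seed
  )
}

#' @method glance perm_test
#' @export
glance.perm_test <- function(x, ...) tidy(x)

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based contrast of between-group versus within-group dissimilarities:
#' `R = (mean rank between - mean rank within) / (M/2)` with `M = n(n-1)/2`
#' mid-ranked pairs; R = 1 means complete separation, R near 0 no structure.
#' The p-value is the add-one-corrected proportion of label permutations
#' with `R_perm >= R_obs` (computed by [vegan::anosim()]).
#'
#' @param dist A symmetric dissimilarity matrix with zero diagonal.
#' @param groups Named vector (or factor) of group labels, one per id; at
#'   least two groups with two members each.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Integer seed.
#' @return A `perm_test` with the ANOSIM R statistic.
#' @export
anosim <- function(dist, groups, n_perm = 9999, seed = 1L) {
  d <- as_distance_matrix(dist)
  check_scalar_int(n_perm, "n_perm", min = 1)
  check_scalar_int(seed, "seed")
  g <- if (!is.null(names(groups))) groups[rownames(d)] else groups
  if (length(g) != nrow(d) || anyNA(g)) abort("`groups` must label every id in `dist`")
  tabg <- table(g)
  if (length(tabg) < 2L) abort("need at least 2 groups")
  if (any(tabg < 2L)) {
    abort(sprintf("group '%s' has fewer than 2 members", names(tabg)[tabg < 2][1L]))
  }
  set.seed(seed)
  fit <- vegan::anosim(stats::as.dist(d), grouping = factor(g), permutations = n_perm)
  new_perm_test(
    method = "ANOSIM", statistic = unname(fit$statistic),
    p_value = fit$signif, n_permutations = n_perm, tail = "greater",
    seed = as.integer(seed), permutations = fit$perm
  )
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower-triangle entries of two distance
#' matrices over the same entities, with significance from permuting the
#' ids of the second matrix. One-tailed in either direction: `tail =
#' "greater"` asks whether the observed correlation is larger than expected
#' by chance, `tail = "less"` whether it is smaller (the convention when
#' testing for community similarity declining with phylogenetic distance).
#'
#' @param d1,d2 Symmetric distance matrices over the same ids (d2 is
#'   realigned to d1's id order; a mismatch in id sets is an error).
#' @param tail `"greater"` or `"less"`.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return A `perm_test` with the Mantel r statistic.
#' @export
mantel <- function(d1, d2, tail = c("greater", "less"), n_perm = 999, seed = 1L) {
  tail <- match.arg(tail)
  check_scalar_int(n_perm, "n_perm", min = 1)
  check_scalar_int(seed, "seed")
  m1 <- as_distance_matrix(d1, "d1")
  m2 <- as_distance_matrix(d2, "d2")
  if (!setequal(rownames(m1), rownames(m2))) {
    abort("`d1` and `d2` must be over the same ids")
  }
  m2 <- m2[rownames(m1), rownames(m1)]
  v1 <- lower_tri_vec(m1)
  v2 <- lower_tri_vec(m2)
  if (var(v1) == 0 || var(v2) == 0) abort("zero variance in a distance matrix")
  r_obs <- cor(v1, v2)
  n <- nrow(m1)
  set.seed(seed)
  r_perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n)
    cor(v1, lower_tri_vec(m2[idx, idx]))
  }, numeric(1))
  hits <- if (tail == "greater") sum(r_perm >= r_obs) else sum(r_perm <= r_obs)
  new_perm_test(
    method = "Mantel", statistic = r_obs,
    p_value = (1 + hits) / (n_perm + 1), n_permutations = n_perm,
    tail = tail, seed = as.integer(seed), permutations = r_perm
  )
}

#' Paired t-test on log-transformed values
#'
#' Tests whether paired positive measurements (e.g. per-host OTU richness
#' of two compartments) differ after natural-log transformation:
#' `t = mean(log a - log b) / (sd / sqrt(n))` on `n - 1` degrees of
#' freedom. One-tailed (`"greater"`, the default: a > b) or two-sided.
#'
#' @param a,b Named positive numeric vectors (or two-column data frames)
#'   over the same ids; `b` is realigned to `a`'s ids.
#' @param tail `"greater"` or `"two-sided"`.
#' @return A `perm_test` with the t statistic and `df`.
#' @export
paired_t_log <- function(a, b, tail = c("greater", "two-sided")) {
  tail <- match.arg(tail)
  av <- as_trait_vector(a)
  bv <- as_trait_vector(b)
  if (!setequal(names(av), names(bv))) abort("`a` and `b` must share the same ids")
  bv <- bv[names(av)]
  if (length(av) < 2L) abort("need at least 2 pairs")
  if (any(av <= 0) || any(bv <= 0)) abort("all values must be positive for the log transform")
  diffs <- log(av) - log(bv)
  if (var(diffs) == 0) abort("log-differences have zero variance; t is undefined")
  alt <- if (tail == "greater") "greater" else "two.sided"
  fit <- t.test(diffs, alternative = alt)
  new_perm_test(
    method = "paired t (log)", statistic = unname(fit$statistic),
    p_value = fit$p.value, n_permutations = NA_integer_, tail = tail,
    df = unname(fit$parameter)
  )
}
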