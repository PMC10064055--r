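#' Patefield sample: random integer table with fixed marginals
#'
#' Uniform draw from the set of nonnegative integer tables with exactly the
#' given row and column sums, via the sequential conditional hypergeometric
#' construction implemented in [stats::r2dtable()] (Patefield's algorithm).
#'
#' @param row_sums,col_sums Nonnegative integer marginal totals with equal
#'   sums.
#' @param seed Integer seed.
#' @return An integer matrix with the requested marginals.
#' @export
patefield_sample <- function(row_sums, col_sums, seed = 1L) {
  check_scalar_int(seed, "seed")
  if (any(row_sums < 0) || any(col_sums < 0) ||
      any(row_sums != round(row_sums)) || any(col_sums != round(col_sums))) {
    abort("marginals must be nonnegative integers")
  }
  if (sum(row_sums) != sum(col_sums)) {
    abort(sprintf(
      "marginal totals disagree: sum(row_sums) = %d, sum(col_sums) = %d",
      sum(row_sums), sum(col_sums)
    ))
  }
  if (sum(row_sums) == 0) abort("marginals must have positive total")
  set.seed(seed)
  if (length(row_sums) == 1L || length(col_sums) == 1L) {
    # a single row or column forces the table
    out <- matrix(as.integer(if (length(row_sums) == 1L) col_sums else row_sums),
                  nrow = length(row_sums))
  } else {
    out <- r2dtable(1, as.integer(row_sums), as.integer(col_sums))[[1L]]
  }
  if (!is.null(names(row_sums))) rownames(out) <- names(row_sums)
  if (!is.null(names(col_sums))) colnames(out) <- names(col_sums)
  out
}

#' Swap-web null matrix: fixed marginals and fixed connectance
#'
#' Randomises a quantitative interaction matrix while preserving its row
#' totals, column totals, and number of filled (nonzero) cells. Starting
#' from a Patefield draw of the observed marginals, 2x2 submatrix weight
#' shifts (moving `min` of a diagonal pair across to the anti-diagonal,
#' which leaves both marginals untouched) are applied, accepting shifts
#' that move the fill toward the observed fill, until the fill matches. If
#' the chain stalls (no accepted directional shift for a long stretch) a
#' fill-neutral shift is accepted to reshuffle before continuing.
#'
#' @param m An [interaction_matrix] with integer weights.
#' @param seed Integer seed.
#' @param max_iter Maximum number of proposed shifts before giving up.
#' @return An [interaction_matrix] with identical marginals and fill.
#' @export
swap_web_null <- function(m, seed = 1L, max_iter = 1e6) {
  w <- im_weights(m)
  check_scalar_int(seed, "seed")
  if (any(w != round(w))) {
    abort("swap-web null needs integer weights (read counts); refusing to round")
  }
  target_fill <- sum(w > 0)
  r <- rowSums(w)
  cc <- colSums(w)
  if (nrow(w) < 2L || ncol(w) < 2L) abort("need at least a 2x2 matrix")
  set.seed(seed)
  cur <- r2dtable(1, as.integer(r), as.integer(cc))[[1L]]
  fill <- sum(cur > 0)
  np <- nrow(cur)
  nf <- ncol(cur)
  stalled <- 0L
  iter <- 0L
  while (fill != target_fill) {
    iter <- iter + 1L
    if (iter > max_iter) {
      abort(sprintf(
        "swap-web: fill %d not reached within %d proposals (achieved %d)",
        target_fill, as.integer(max_iter), fill
      ))
    }
    i <- sample.int(np, 2L)
    j <- sample.int(nf, 2L)
    x11 <- cur[i[1L], j[1L]]; x12 <- cur[i[1L], j[2L]]
    x21 <- cur[i[2L], j[1L]]; x22 <- cur[i[2L], j[2L]]
    need <- sign(target_fill - fill)
    # direction A: drain the (11, 22) diagonal into (12, 21)
    ta <- min(x11, x22)
    da <- if (ta > 0) (x12 == 0) + (x21 == 0) - (x11 == ta) - (x22 == ta) else NA_integer_
    # direction B: drain the (12, 21) anti-diagonal into (11, 22)
    tb <- min(x12, x21)
    db <- if (tb > 0) (x11 == 0) + (x22 == 0) - (x12 == tb) - (x21 == tb) else NA_integer_
    pick <- NULL
    ok_a <- !is.na(da) && sign(da) == need
    ok_b <- !is.na(db) && sign(db) == need
    if (ok_a && ok_b) {
      pick <- if (runif(1) < 0.5) "A" else "B"
    } else if (ok_a) {
      pick <- "A"
    } else if (ok_b) {
      pick <- "B"
    } else {
      stalled <- stalled + 1L
      if (stalled > 5000L) {
        # no directional move found for a long stretch (can happen for very
        # dense targets): restart the chain from a fresh marginal draw
        cur <- r2dtable(1, as.integer(r), as.integer(cc))[[1L]]
        fill <- sum(cur > 0)
        stalled <- 0L
        next
      }
      if (stalled > 500L) {
        # accept a fill-neutral shift to reshuffle out of the local trap
        if (!is.na(da) && da == 0L) pick <- "A" else if (!is.na(db) && db == 0L) pick <- "B"
      }
      if (is.null(pick)) next
    }
    stalled <- 0L
    if (pick == "A") {
      cur[i[1L], j[1L]] <- x11 - ta
      cur[i[2L], j[2L]] <- x22 - ta
      cur[i[1L], j[2L]] <- x12 + ta
      cur[i[2L], j[1L]] <- x21 + ta
      fill <- fill + da
    } else {
      cur[i[1L], j[2L]] <- x12 - tb
      cur[i[2L], j[1L]] <- x21 - tb
      cur[i[1L], j[1L]] <- x11 + tb
      cur[i[2L], j[2L]] <- x22 + tb
      fill <- fill + db
    }
  }
  dimnames(cur) <- dimnames(w)
  interaction_matrix(cur)
}

metric_registry <- function() {
  list(
    h2 = specialization_h2,
    connectance = weighted_connectance,
    wnodf = wnodf
  )
}

resolve_metric <- function(metric, n_restarts, seed) {
  if (is.function(metric)) {
    return(list(fn = metric, name = "custom"))
  }
  metric <- match.arg(metric, c("h2", "modularity", "connectance", "wnodf"))
  if (metric == "modularity") {
    fn <- function(m) bipartite_modularity(m, n_restarts = n_restarts, seed = seed)$Q
  } else {
    fn <- metric_registry()[[metric]]
  }
  list(fn = fn, name = metric)
}

new_null_ensemble <- function(metric_name, obs, null_values, seed) {
  exp_ <- mean(null_values)
  sd_ <- sd(null_values)
  degenerate <- !is.finite(sd_) || sd_ == 0
  z <- if (degenerate) NA_real_ else (obs - exp_) / sd_
  p <- (1 + sum(abs(null_values - exp_) >= abs(obs - exp_))) / (length(null_values) + 1)
  structure(
    list(
      metric_name = metric_name, obs = obs, null_values = null_values,
      exp = exp_, sd_exp = sd_, z = z, p_two_sided = p,
      degenerate = degenerate, n_null = length(null_values),
      seed = as.integer(seed)
    ),
    class = "null_ensemble"
  )
}

#' Standardize a network metric against swap-web nulls
#'
#' Computes the observed metric and its value on `n_null` independent
#' swap-web randomisations (identical marginal totals and connectance) and
#' reports the z-score `z = (obs - exp) / sd_exp`, where `exp` and
#' `sd_exp` are the mean and standard deviation over the null ensemble,
#' plus a two-sided add-one-corrected empirical p-value. When the null
#' standard deviation is zero, `z` is `NA` and the ensemble is flagged
#' degenerate rather than reporting an infinity.
#'
#' @param m An [interaction_matrix] with integer weights.
#' @param metric `"h2"`, `"modularity"`, `"connectance"`, `"wnodf"`, or a
#'   function taking an interaction matrix and returning a scalar.
#' @param n_null Number of null matrices (default 1000).
#' @param seed Integer seed; null i uses the derived seed `seed + i`.
#' @param n_restarts Restarts for the modularity optimiser (observed and
#'   null alike).
#' @return A `null_ensemble`; see [glance.null_ensemble()].
#' @export
standardize_metric <- function(m, metric, n_null = 1000, seed = 1L, n_restarts = 10) {
  m <- interaction_matrix(m)
  check_scalar_int(n_null, "n_null", min = 2)
  check_scalar_int(seed, "seed")
  res <- resolve_metric(metric, n_restarts, seed)
  obs <- res$fn(m)
  nulls <- vapply(seq_len(n_null), function(i) {
    res$fn(swap_web_null(m, seed = stage_seed(seed, paste0("null", i))))
  }, numeric(1))
  new_null_ensemble(res$name, obs, nulls, seed)
}

#' Standardize all four network metrics on one shared null ensemble
#'
#' Generates one swap-web ensemble and evaluates H2', modularity Q,
#' weighted connectance and WNODF on every member, so the four z-scores of
#' a network are mutually comparable and the ensemble cost is paid once.
#'
#' @inheritParams standardize_metric
#' @return A named list of four `null_ensemble` objects
#'   (`h2`, `modularity`, `connectance`, `wnodf`).
#' @export
network_null_report <- function(m, n_null = 1000, seed = 1L, n_restarts = 10) {
  m <- interaction_matrix(m)
  check_scalar_int(n_null, "n_null", min = 2)
  fns <- list(
    h2 = specialization_h2,
    modularity = function(x) bipartite_modularity(x, n_restarts = n_restarts, seed = seed)$Q,
    connectance = weighted_connectance,
    wnodf = wnodf
  )
  obs <- lapply(fns, function(f) f(m))
  vals <- matrix(NA_real_, n_null, length(fns), dimnames = list(NULL, names(fns)))
  for (i in seq_len(n_null)) {
    null_m <- swap_web_null(m, seed = stage_seed(seed, paste0("null", i)))
    for (nm in names(fns)) vals[i, nm] <- fns[[nm]](null_m)
  }
  out <- lapply(names(fns), function(nm) {
    new_null_ensemble(nm, obs[[nm]], vals[, nm], seed)
  })
  names(out) <- names(fns)
  out
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf(
    "%s: obs = %.4g, exp = %.4g +/- %.4g (n_null = %d)\n  z = %s, two-sided p = %.4g%s\n",
    x$metric_name, x$obs, x$exp, x$sd_exp, x$n_null,
    if (x$degenerate) "NA (degenerate: sd_exp = 0)" else sprintf("%.3f", x$z),
    x$p_two_sided, if (x$degenerate) " [degenerate]" else ""
  ))
  invisible(x)
}

#' Tidy / summarise a null ensemble
#'
#' `tidy()` returns the null metric values one per row; `glance()` the
#' one-row summary (observed value, null mean and sd, z, p).
#'
#' @param x A `null_ensemble` from [standardize_metric()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy null_ensemble
#' @export
tidy.null_ensemble <- function(x, ...) {
  tibble(metric = x$metric_name, draw = seq_len(x$n_null), value = x$null_values)
}

#' @rdname tidy.null_ensemble
#' @method glance null_ensemble
#' @export
glance.null_ensemble <- function(x, ...) {
  tibble(
    metric = x$metric_name, obs = x$obs, exp = x$exp, sd_exp = x$sd_exp,
    z = x$z, p_two_sided = x$p_two_sided, n_null = x$n_null,
    degenerate = x$degenerate, seed = x$seed
  )
}

#' @method autoplot null_ensemble
#' @export
autoplot.null_ensemble <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::geom_vline(xintercept = object$obs, colour = "red") +
    ggplot2::labs(
      x = object$metric_name,
      title = sprintf(
        "%s: obs %.3g vs null %.3g +/- %.3g (z = %.2f)",
        object$metric_name, object$obs, object$exp, object$sd_exp,
        ifelse(object$degenerate, NA, object$z)
      )
    )
}
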