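#' Simulate secondary extinctions under random primary removals
#'
#' Species of the primary guild (plants or fungi) are removed in uniformly
#' random order; a species of the other guild goes secondarily extinct once
#' every one of its interaction partners has been removed (a topological
#' rule on the nonzero pattern: weights do not modulate the threshold).
#' The surviving proportion is averaged over replicates at each removal
#' step, giving the attack-tolerance curve y(x) with x the proportion of
#' the primary guild removed.
#'
#' @param m An [interaction_matrix].
#' @param primary_axis `"plants"` (remove rows) or `"fungi"` (remove columns).
#' @param n_rep Number of random removal orders to average (default 100).
#' @param seed Integer seed.
#' @return An `extinction_curve`: tibble with columns `x` (0 to 1 in steps
#'   of 1/n_primary) and `y` (mean surviving proportion of the secondary
#'   guild), with attributes `primary_axis`, `n_rep`, `seed`.
#' @export
simulate_extinctions <- function(m, primary_axis = c("plants", "fungi"),
                                 n_rep = 100, seed = 1L) {
  primary_axis <- match.arg(primary_axis)
  check_scalar_int(n_rep, "n_rep", min = 1)
  check_scalar_int(seed, "seed")
  w <- im_weights(m)
  adj <- w > 0
  if (primary_axis == "fungi") adj <- t(adj)
  n_primary <- nrow(adj)
  n_secondary <- ncol(adj)
  set.seed(seed)
  surv <- numeric(n_primary + 1L)
  for (rep in seq_len(n_rep)) {
    ord <- sample.int(n_primary)
    pos <- integer(n_primary)
    pos[ord] <- seq_len(n_primary)
    # a secondary species survives step k iff some partner is removed later
    ext_step <- apply(adj, 2, function(col) max(pos[col]))
    surv <- surv + vapply(0:n_primary, function(k) sum(ext_step > k), numeric(1))
  }
  out <- tibble(
    x = (0:n_primary) / n_primary,
    y = surv / (n_rep * n_secondary)
  )
  structure(out,
    class = c("extinction_curve", class(out)),
    primary_axis = primary_axis, n_rep = as.integer(n_rep),
    seed = as.integer(seed)
  )
}

#' Fit the exponential extinction model y = 1 - x^a
#'
#' Least-squares fit of the one-parameter exponential regression model
#' `y = 1 - x^a` (a > 0) to an extinction curve, by scalar minimisation of
#' the residual sum of squares over `log(a)`. The fitted robustness is the
#' closed-form area below the curve, `R = integral(1 - x^a) = a / (a + 1)`;
#' the empirical area by the trapezoid rule is reported alongside since a
#' published curve may quote either. Flat degenerate curves (all y = 1)
#' admit no finite exponent and raise an error.
#'
#' @param curve An `extinction_curve` (or data frame with `x`, `y`).
#' @return A `robustness_fit`: list with `a`, `R_fitted = a/(a+1)`,
#'   `R_empirical`, `rss`, `primary_axis`.
#' @export
fit_extinction_curve <- function(curve) {
  x <- curve$x
  y <- curve$y
  if (length(x) < 3L) abort("need at least 3 curve points")
  if (is.unsorted(x, strictly = TRUE)) abort("`x` must be strictly increasing")
  r_emp <- sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  if (all(y >= 1 - 1e-12)) {
    abort(sprintf(
      "degenerate curve: y = 1 everywhere, no finite exponent (empirical area = %.4f)",
      r_emp
    ))
  }
  sse <- function(log_a) {
    a <- exp(log_a)
    sum((y - (1 - x^a))^2)
  }
  opt <- optimize(sse, interval = c(-12, 12))
  a <- exp(opt$minimum)
  structure(
    list(
      a = a, R_fitted = a / (a + 1), R_empirical = r_emp, rss = opt$objective,
      primary_axis = attr(curve, "primary_axis") %||% NA_character_
    ),
    class = "robustness_fit"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.robustness_fit <- function(x, ...) {
  cat(sprintf(
    "Extinction fit y = 1 - x^a: a = %.3f, R (fitted) = %.3f, R (empirical) = %.3f\n",
    x$a, x$R_fitted, x$R_empirical
  ))
  invisible(x)
}

#' @method glance robustness_fit
#' @export
glance.robustness_fit <- function(x, ...) {
  tibble(
    a = x$a, R_fitted = x$R_fitted, R_empirical = x$R_empirical,
    rss = x$rss, primary_axis = x$primary_axis
  )
}

#' @method tidy robustness_fit
#' @export
tidy.robustness_fit <- function(x, ...) glance(x)

#' @method autoplot extinction_curve
#' @export
autoplot.extinction_curve <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = sprintf("proportion of %s removed", attr(object, "primary_axis")),
      y = "proportion of partner guild surviving"
    ) +
    ggplot2::ylim(0, 1)
  if (!is.null(fit)) {
    xs <- seq(0, 1, length.out = 200)
    p <- p + ggplot2::geom_line(
      data = tibble(x = xs, y = 1 - xs^fit$a),
      colour = "red", linetype = 2
    )
  }
  p
}
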