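#' Weighted posterior sample container
#'
#' A labelled set of weighted posterior draws: one column per parameter plus
#' a `weight` column (normalised to sum to one).
#'
#' @param draws Data frame of parameter draws (numeric columns).
#' @param weights Non-negative weights, recycled/normalised; default equal.
#' @param label Run label, e.g. `"orig"`, `"scratch"`, `"seq"`.
#' @return A `posterior_sample` tibble with attribute `label`.
#' @export
posterior_sample <- function(draws, weights = NULL, label = "run") {
  draws <- tibble::as_tibble(draws)
  draws <- draws[, vapply(draws, is.numeric, logical(1)), drop = FALSE]
  draws$weight <- NULL
  n <- nrow(draws)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0), sum(weights) > 0)
  out <- draws
  out$weight <- weights / sum(weights)
  attr(out, "label") <- label
  class(out) <- c("posterior_sample", class(out))
  out
}

#' @rdname posterior_sample
#' @param state An `imabc_state`.
#' @export
as_posterior_sample <- function(state, label = "run") {
  posterior_sample(state$draws[, state$prior$name, drop = FALSE],
                   state$weights, label = label)
}

#' Weighted quantiles and equal-tailed credible interval
#'
#' Quantiles use the inverse of the right-continuous weighted empirical
#' CDF: the smallest draw whose cumulative weight reaches the requested
#' probability. With equal weights on `1..100`, the 95% interval is
#' `(3, 98)`.
#'
#' @param x Draws.
#' @param w Weights (any positive scale).
#' @param probs Probabilities.
#' @return `weighted_quantile()`: quantiles; `credible_interval()`: a named
#'   vector `c(lower, upper)`.
#' @export
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), length(x) >= 1)
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  vapply(probs, function(p) x[o][which(cw >= p - 1e-12)[1]], numeric(1))
}

#' @rdname weighted_quantile
#' @param sample A [posterior_sample()] (or any data frame with a `weight`
#'   column).
#' @param parameter Column name.
#' @param level Credible level.
#' @export
credible_interval <- function(sample, parameter, level = 0.95) {
  x <- sample[[parameter]]
  if (is.null(x) || length(x) == 0) stop("empty sample for ", parameter)
  w <- sample$weight
  if (is.null(w)) w <- rep(1, length(x))
  a <- (1 - level) / 2
  q <- weighted_quantile(x, w, c(a, 1 - a))
  c(lower = q[1], upper = q[2])
}

#' Credible-interval overlap measure
#'
#' For two overlapping intervals `(L1, U1)` and `(L2, U2)` with
#' intersection `(LI, UI)`:
#' \deqn{0.5\,(U_I-L_I)/(U_1-L_1) + 0.5\,(U_I-L_I)/(U_2-L_2),}
#' the average of the fraction of each interval contained in their
#' intersection: 1 for identical intervals, 0 for disjoint ones.
#'
#' @param interval1,interval2 Numeric length-2 vectors `(lower, upper)`.
#' @return Overlap score in `[0, 1]`.
#' @export
#' @examples
#' ci_overlap(c(2.20, 4.92), c(2.02, 3.07)) # ~0.57
ci_overlap <- function(interval1, interval2) {
  l1 <- interval1[1]; u1 <- interval1[2]
  l2 <- interval2[1]; u2 <- interval2[2]
  if (!(l1 < u1) || !(l2 < u2)) stop("degenerate (zero-width) interval")
  li <- max(l1, l2); ui <- min(u1, u2)
  if (ui <= li) return(0)
  unname(0.5 * (ui - li) / (u1 - l1) + 0.5 * (ui - li) / (u2 - l2))
}

# shared weighted Gaussian KDE on a fixed grid ------------------------------

weighted_sd <- function(x, w) {
  w <- w / sum(w)
  m <- sum(w * x)
  sqrt(max(0, sum(w * (x - m)^2)))
}

silverman_bw <- function(x, w) {
  n_eff <- ess(w)
  s <- weighted_sd(x, w)
  q <- weighted_quantile(x, w, c(0.25, 0.75))
  iqr <- q[2] - q[1]
  sig <- min(s, if (iqr > 0) iqr / 1.349 else s)
  if (sig <= 0) stop("degenerate (zero-variance) sample")
  0.9 * sig * n_eff^(-1 / 5)
}

kde_on_grid <- function(x, w, grid, bw) {
  w <- w / sum(w)
  # f(g) = sum_i w_i K((g - x_i)/h)/h
  z <- outer(grid, x, "-") / bw
  as.vector(exp(-z^2 / 2) %*% w) / (bw * sqrt(2 * pi))
}

shared_kde <- function(x1, w1, x2, w2, n_grid = 512) {
  bw1 <- silverman_bw(x1, w1)
  bw2 <- silverman_bw(x2, w2)
  pad <- 3 * max(bw1, bw2)
  lo <- min(x1, x2) - pad
  hi <- max(x1, x2) + pad
  grid <- seq(lo, hi, length.out = n_grid)
  list(grid = grid,
       f1 = kde_on_grid(x1, w1, grid, bw1),
       f2 = kde_on_grid(x2, w2, grid, bw2))
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

get_xw <- function(sample, parameter, weighted = TRUE) {
  x <- sample[[parameter]]
  if (is.null(x)) stop("no column ", parameter)
  if (length(x) < 10) stop("need at least 10 draws for density estimates")
  w <- if (weighted && !is.null(sample$weight)) sample$weight else rep(1, length(x))
  list(x = x, w = w)
}

#' Area overlap of two empirical posterior densities
#'
#' \eqn{\int \min(\hat f_1, \hat f_2)} over a shared grid, where the
#' \eqn{\hat f} are weighted Gaussian kernel density estimates with
#' Silverman bandwidths on a 512-point grid spanning the pooled sample range
#' plus three bandwidths.
#'
#' @param sample1,sample2 [posterior_sample()] objects (or data frames with
#'   a `weight` column).
#' @param parameter Column to compare.
#' @param weighted Use the stored weights (`FALSE`: unweighted draws).
#' @return Overlap in `[0, 1]`; near 1 for near-identical distributions.
#' @export
area_overlap <- function(sample1, sample2, parameter, weighted = TRUE) {
  a <- get_xw(sample1, parameter, weighted)
  b <- get_xw(sample2, parameter, weighted)
  k <- shared_kde(a$x, a$w, b$x, b$w)
  min(1, max(0, trapz(k$grid, pmin(k$f1, k$f2))))
}

#' Hellinger distance between two empirical posteriors
#'
#' \eqn{\sqrt{1 - \int\sqrt{\hat f_1 \hat f_2}}} on the shared KDE grid of
#' [area_overlap()]: 0 for identical distributions, 1 for disjoint support.
#'
#' @inheritParams area_overlap
#' @return Distance in `[0, 1]`.
#' @export
hellinger_distance <- function(sample1, sample2, parameter, weighted = TRUE) {
  a <- get_xw(sample1, parameter, weighted)
  b <- get_xw(sample2, parameter, weighted)
  k <- shared_kde(a$x, a$w, b$x, b$w)
  bc <- min(1, max(0, trapz(k$grid, sqrt(k$f1 * k$f2))))
  sqrt(1 - bc)
}

#' Standardized mean difference
#'
#' Absolute difference in (weighted) posterior means, standardised by the
#' posterior standard deviation of the *reference* sample (the original
#' calibration).
#'
#' @param sample1 Reference sample (its sd standardises).
#' @param sample2 Comparison sample.
#' @inheritParams area_overlap
#' @return `|mean2 - mean1| / sd1`.
#' @export
standardized_mean_difference <- function(sample1, sample2, parameter,
                                         weighted = TRUE) {
  a <- get_xw2(sample1, parameter, weighted)
  b <- get_xw2(sample2, parameter, weighted)
  m1 <- sum(a$w * a$x) / sum(a$w)
  m2 <- sum(b$w * b$x) / sum(b$w)
  s1 <- weighted_sd(a$x, a$w)
  if (s1 <= 0) stop("reference sample has zero standard deviation")
  abs(m2 - m1) / s1
}

# like get_xw but without the >= 10 draw requirement (moments only)
get_xw2 <- function(sample, parameter, weighted = TRUE) {
  x <- sample[[parameter]]
  if (is.null(x) || length(x) == 0) stop("no column ", parameter)
  w <- if (weighted && !is.null(sample$weight)) sample$weight else rep(1, length(x))
  list(x = x, w = w)
}

#' Compare two posterior sample sets parameter by parameter
#'
#' Emits the four agreement metrics for each shared parameter column:
#' 95% credible-interval overlap, density area overlap, standardized mean
#' difference (standardised by `sample1`'s sd) and Hellinger distance.
#'
#' @inheritParams standardized_mean_difference
#' @param parameters Columns to compare (default: all shared numeric
#'   columns except `weight`).
#' @param level Credible level for the interval overlap.
#' @return A tibble with columns `parameter`, `ci_overlap`, `area_overlap`,
#'   `smd`, `hellinger`.
#' @export
compare_posteriors <- function(sample1, sample2, parameters = NULL,
                               level = 0.95, weighted = TRUE) {
  if (is.null(parameters)) {
    parameters <- setdiff(intersect(names(sample1), names(sample2)),
                          c("weight", "draw_id", "seed", "stage"))
  }
  rows <- lapply(parameters, function(p) {
    tibble::tibble(
      parameter = p,
      ci_overlap = ci_overlap(credible_interval(sample1, p, level),
                              credible_interval(sample2, p, level)),
      area_overlap = area_overlap(sample1, sample2, p, weighted),
      smd = standardized_mean_difference(sample1, sample2, p, weighted),
      hellinger = hellinger_distance(sample1, sample2, p, weighted)
    )
  })
  dplyr::bind_rows(rows)
}

#' Posterior mean sojourn time
#'
#' Transforms each draw's sojourn parameters to the closed-form mean
#' sojourn time — \eqn{\lambda_1\Gamma(1+1/\lambda_2)} (colon),
#' \eqn{\lambda_1 e^{\lambda_3}\Gamma(1+1/\lambda_2)} (rectum) — and
#' summarises the transformed draws (weighted mean and equal-tailed 95%
#' interval). The summary is the mean of the transformed draws, not the
#' transform of the posterior-mean parameters.
#'
#' @param sample A [posterior_sample()] containing `lambda1`, `lambda2`,
#'   `lambda3` columns.
#' @param level Credible level.
#' @return A tibble with one row per location: `location`, `mean`,
#'   `lower`, `upper`.
#' @export
mst_posterior <- function(sample, level = 0.95) {
  l1 <- sample$lambda1; l2 <- sample$lambda2; l3 <- sample$lambda3
  if (is.null(l1) || is.null(l2) || is.null(l3)) {
    stop("sample must contain lambda1, lambda2, lambda3 columns")
  }
  if (any(l1 <= 0) || any(l2 <= 0)) stop("non-positive lambda1 or lambda2 draw")
  w <- sample$weight
  if (is.null(w)) w <- rep(1, length(l1))
  w <- w / sum(w)
  colon <- l1 * gamma(1 + 1 / l2)
  rectum <- colon * exp(l3)
  a <- (1 - level) / 2
  summ <- function(x, loc) {
    q <- weighted_quantile(x, w, c(a, 1 - a))
    tibble::tibble(location = loc, mean = sum(w * x), lower = q[1], upper = q[2])
  }
  dplyr::bind_rows(summ(colon, "colon"), summ(rectum, "rectum"))
}

#' Density overlay of one parameter across runs
#'
#' @param object A [posterior_sample()].
#' @param ... Further `posterior_sample` objects to overlay.
#' @param parameter Column to plot.
#' @return A ggplot object.
#' @export
autoplot.posterior_sample <- function(object, ..., parameter) {
  samples <- c(list(object), list(...))
  dens <- dplyr::bind_rows(lapply(samples, function(s) {
    a <- get_xw(s, parameter)
    bw <- silverman_bw(a$x, a$w)
    grid <- seq(min(a$x) - 3 * bw, max(a$x) + 3 * bw, length.out = 512)
    lab <- attr(s, "label"); if (is.null(lab)) lab <- "run"
    tibble::tibble(x = grid, density = kde_on_grid(a$x, a$w, grid, bw),
                   run = lab)
  }))
  ggplot2::ggplot(dens, ggplot2::aes(x = .data$x, y = .data$density,
                                     colour = .data$run)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = parameter, y = "posterior density", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heat-style summary plot of a posterior comparison table
#'
#' @param object A tibble from [compare_posteriors()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(object, -"parameter",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$parameter,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$value))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL)
}
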