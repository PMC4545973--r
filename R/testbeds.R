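#' Analytic testbed simulators
#'
#' Two minimal simulators whose optimization posteriors are available in
#' closed form (via [analytic_pope_posterior()]), used to validate the
#' samplers: a Gaussian location simulator `y = theta + sigma * z` with
#' standard normal `z`, and a deterministic quadratic `y = sum(theta^2)`.
#'
#' @param sigma noise standard deviation (>= 0).
#' @return `gaussian_test_simulator` returns a simulator closure
#'   `function(theta) -> y` drawing from the current RNG stream;
#'   `quadratic_test_simulator` returns the deterministic closure.
#' @export
gaussian_test_simulator <- function(sigma = 0.5) {
  stopifnot(sigma >= 0)
  function(theta) theta[1] + sigma * stats::rnorm(1)
}

#' @rdname gaussian_test_simulator
#' @export
quadratic_test_simulator <- function() {
  function(theta) sum(theta^2)
}

#' Closed-form optimization posterior on a grid
#'
#' The target density `pi(theta | y*) \propto pi(theta) * F(y* | theta)`
#' evaluated pointwise and normalized by trapezoidal quadrature.  For the
#' Gaussian testbed `F(y* | theta) = pnorm((y* - m(theta)) / sigma)`; with
#' `sigma = 0` the CDF degrades to the indicator `[m(theta) <= y*]`, i.e.
#' the prior restricted to the feasible set.
#'
#' @param prior_density vectorized prior density function of `theta`.
#' @param sigma simulator noise standard deviation.
#' @param y_star objective threshold.
#' @param grid numeric vector of `theta` values covering the effective
#'   prior support.
#' @param mean_fn simulator mean function `m(theta)` (identity by
#'   default; use `function(t) t^2` for the quadratic testbed).
#' @return list with `grid`, `density` (normalized), `cdf`, and `mean`
#'   (posterior mean by quadrature).
#' @export
analytic_pope_posterior <- function(prior_density, sigma, y_star, grid,
                                    mean_fn = identity) {
  m <- mean_fn(grid)
  lik <- if (sigma == 0) as.numeric(m <= y_star) else
    stats::pnorm((y_star - m) / sigma)
  f <- prior_density(grid) * lik
  dgrid <- diff(grid)
  trapz <- sum(dgrid * (f[-1] + f[-length(f)]) / 2)
  if (trapz <= 0) stop("posterior has zero mass on the supplied grid")
  dens <- f / trapz
  cdf <- c(0, cumsum(dgrid * (dens[-1] + dens[-length(dens)]) / 2))
  cdf <- pmin(cdf / cdf[length(cdf)], 1)
  mean_post <- sum(dgrid * ((grid * dens)[-1] + (grid * dens)[-length(grid)]) / 2)
  list(grid = grid, density = dens, cdf = cdf, mean = mean_post)
}

#' Kolmogorov-Smirnov distance between samples and a grid CDF
#'
#' Sup distance between the empirical CDF of `samples` and a reference
#' CDF tabulated on a grid (linearly interpolated), as produced by
#' [analytic_pope_posterior()].
#'
#' @param samples numeric sample vector.
#' @param grid,cdf reference grid and CDF values.
#' @return the KS distance.
#' @export
ks_distance <- function(samples, grid, cdf) {
  x <- sort(samples)
  n <- length(x)
  Fx <- stats::approx(grid, cdf, xout = x, yleft = 0, yright = 1)$y
  max(abs(Fx - seq_len(n) / n), abs(Fx - (seq_len(n) - 1) / n))
}
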