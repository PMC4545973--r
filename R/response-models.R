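#' Fit a conditional Gaussian (synthetic likelihood) response model
#'
#' Fits the first two moments of `S` simulator draws at a fixed parameter
#' value: the sample mean and the unbiased (`S - 1` denominator) sample
#' covariance.  The fitted Gaussian stands in for the simulator response
#' distribution and yields analytic CDF likelihoods via
#' [gaussian_cdf_likelihood()], an alternative to kernel-based ABC
#' likelihoods.
#'
#' @param draws numeric matrix of simulator outputs, `S` rows (draws) by
#'   `J` columns (statistics); a vector is treated as `J = 1`.
#' @param factorized logical; keep only the per-statistic variances
#'   (product-of-marginals model).  Default `TRUE`, which is what the CDF
#'   computation for `J > 1` requires.
#' @return an object of class `conditional_gaussian` with elements
#'   `mu_hat`, `sigma_hat` (covariance matrix, or vector of variances when
#'   factorized), `S`, `factorized`, and `degenerate` (`TRUE` when any
#'   retained variance is zero, in which case the CDF degrades to a hard
#'   indicator at the mean).
#' @export
#' @examples
#' m <- fit_conditional_gaussian(c(0, 2))
#' m$mu_hat     # 1
#' m$sigma_hat  # 2 (unbiased variance of {0, 2})
fit_conditional_gaussian <- function(draws, factorized = TRUE) {
  if (is.vector(draws)) draws <- matrix(draws, ncol = 1)
  draws <- as.matrix(draws)
  S <- nrow(draws)
  if (S < 2) stop("synthetic likelihood needs S >= 2 draws (S - 1 denominator)")
  mu <- colMeans(draws)
  if (factorized) {
    sig <- apply(draws, 2, stats::var)
    degenerate <- any(sig == 0)
  } else {
    sig <- stats::cov(draws)
    degenerate <- any(diag(sig) == 0)
  }
  structure(list(mu_hat = mu, sigma_hat = sig, S = S,
                 factorized = isTRUE(factorized), degenerate = degenerate),
            class = "conditional_gaussian")
}

#' @export
print.conditional_gaussian <- function(x, ...) {
  cat(sprintf("<conditional Gaussian> J=%d, S=%d, %s%s\n", length(x$mu_hat),
              x$S, if (x$factorized) "factorized" else "full covariance",
              if (x$degenerate) ", degenerate (zero variance)" else ""))
  invisible(x)
}

# Per-constraint normal probability under a fitted marginal N(mu, sd^2).
# Zero sd degrades to the indicator at mu (limit of the normal CDF).
normal_constraint_prob <- function(mu, sd, spec) {
  if (sd == 0) return(as.numeric(constraint_violation(mu, spec) <= 0))
  switch(spec$direction,
         LE = stats::pnorm(spec$threshold, mu, sd),
         GE = stats::pnorm(spec$threshold, mu, sd, lower.tail = FALSE),
         INTERVAL = stats::pnorm(spec$threshold[2], mu, sd) -
           stats::pnorm(spec$threshold[1], mu, sd))
}

#' CDF likelihood from a fitted conditional Gaussian
#'
#' Computes the probability, under the fitted response model, that every
#' constraint is satisfied: a product over constraints of normal
#' orthant/interval probabilities `pnorm((y* - mu)/sd)` (LE), its
#' complement (GE), or `pnorm(b) - pnorm(a)` (INTERVAL).  This is the
#' optimization-posterior likelihood evaluated analytically instead of by
#' kernel-weighted simulation counts.
#'
#' The product form assumes independent statistics, so the model must be
#' factorized; a full-covariance model is accepted only for a single
#' statistic.
#'
#' @param model a [fit_conditional_gaussian()] result.
#' @param specs list of [constraint_spec()] objects.
#' @return probability in `[0, 1]`.
#' @export
gaussian_cdf_likelihood <- function(model, specs) {
  stopifnot(inherits(model, "conditional_gaussian"))
  J <- length(model$mu_hat)
  if (model$factorized) {
    sds <- sqrt(model$sigma_hat)
  } else {
    if (J > 1)
      stop("full-covariance CDF is supported only for J = 1; fit with factorized = TRUE")
    sds <- sqrt(diag(as.matrix(model$sigma_hat)))
  }
  idx <- vapply(specs, function(s) s$statistic, integer(1))
  if (any(idx > J)) stop("constraint statistic index exceeds model dimension")
  prod(vapply(specs, function(s)
    normal_constraint_prob(model$mu_hat[s$statistic], sds[s$statistic], s),
    numeric(1)))
}

# CDF likelihood against a compact spec table (internal hot path).
gaussian_cdf_tab <- function(model, tab) {
  sds <- sqrt(model$sigma_hat)
  p <- 1
  for (k in seq_len(nrow(tab))) {
    mu <- model$mu_hat[tab[k, "idx"]]
    sd <- sds[tab[k, "idx"]]
    lo <- tab[k, "lo"]; hi <- tab[k, "hi"]
    pk <- if (sd == 0) {
      as.numeric(mu >= lo && mu <= hi)
    } else {
      (if (is.finite(hi)) stats::pnorm(hi, mu, sd) else 1) -
        (if (is.finite(lo)) stats::pnorm(lo, mu, sd) else 0)
    }
    p <- p * pk
  }
  as.numeric(p)
}

#' Monte-Carlo CDF estimate of the constraint probability
#'
#' The direct simulation estimate of the one-sided ABC likelihood: the
#' average over draws of the product of per-constraint indicators (hard
#' version) or of the soft composite kernel likelihood (`soft = TRUE`).
#'
#' @param draws `S x J` matrix of simulator outputs (vector for `J = 1`).
#' @param specs list of [constraint_spec()] objects.
#' @param soft logical; use the specs' own (possibly soft) kernels instead
#'   of hard indicators.
#' @return estimated probability in `[0, 1]`.
#' @export
#' @examples
#' specs <- list(constraint_spec(1, "LE", 2.5, kernel = "heavyside"))
#' monte_carlo_cdf(c(1, 2, 3, 4), specs)  # 0.5
monte_carlo_cdf <- function(draws, specs, soft = FALSE) {
  if (is.vector(draws)) draws <- matrix(draws, ncol = 1)
  S <- nrow(draws)
  if (S < 1) stop("monte_carlo_cdf needs at least one draw")
  if (soft) {
    mean(vapply(seq_len(S), function(s)
      exp(composite_log_likelihood(draws[s, ], specs)), numeric(1)))
  } else {
    mean(vapply(seq_len(S), function(s)
      all(vapply(specs, function(sp)
        constraint_violation(draws[s, sp$statistic], sp) <= 0, logical(1))),
      numeric(1)))
  }
}
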