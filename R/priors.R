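#' Marginal prior distributions
#'
#' Building blocks for [pope_prior()].  Each constructor returns a marginal
#' prior with a density, a sampler, a support declaration (used by the
#' sampler to pick the random-walk transform: identity on the real line,
#' log for positive parameters, logit for interval-bounded ones), and a
#' nominal standard deviation used for default proposal scales.
#'
#' @param mean,sd,min,max,meanlog,sdlog,shape1,shape2 the usual
#'   distribution parameters.
#' @return an object of class `pope_marginal_prior`.
#' @name marginal_priors
NULL

marginal_prior <- function(type, logpdf, sample, support, sd) {
  structure(list(type = type, logpdf = logpdf, sample = sample,
                 support = support, sd = sd),
            class = "pope_marginal_prior")
}

#' @rdname marginal_priors
#' @export
prior_normal <- function(mean = 0, sd = 1) {
  marginal_prior("normal",
                 function(x) stats::dnorm(x, mean, sd, log = TRUE),
                 function(n) stats::rnorm(n, mean, sd),
                 support = c(-Inf, Inf), sd = sd)
}

#' @rdname marginal_priors
#' @export
prior_uniform <- function(min = 0, max = 1) {
  stopifnot(min < max)
  marginal_prior("uniform",
                 function(x) stats::dunif(x, min, max, log = TRUE),
                 function(n) stats::runif(n, min, max),
                 support = c(min, max), sd = (max - min) / sqrt(12))
}

#' @rdname marginal_priors
#' @export
prior_lognormal <- function(meanlog = 0, sdlog = 1) {
  m <- exp(meanlog + sdlog^2 / 2)
  marginal_prior("lognormal",
                 function(x) stats::dlnorm(x, meanlog, sdlog, log = TRUE),
                 function(n) stats::rlnorm(n, meanlog, sdlog),
                 support = c(0, Inf),
                 sd = sqrt((exp(sdlog^2) - 1)) * m)
}

#' @rdname marginal_priors
#' @export
prior_beta <- function(shape1 = 2, shape2 = 2) {
  marginal_prior("beta",
                 function(x) stats::dbeta(x, shape1, shape2, log = TRUE),
                 function(n) stats::rbeta(n, shape1, shape2),
                 support = c(0, 1),
                 sd = sqrt(shape1 * shape2 /
                             ((shape1 + shape2)^2 * (shape1 + shape2 + 1))))
}

#' Joint prior over simulator parameters
#'
#' Assembles independent marginal priors into the joint prior object the
#' sampler consumes.  For priors that are only known up to a constant
#' (e.g. the soft-kernel geometry prior of the stem-cell niche case) use
#' [pope_prior_custom()].
#'
#' @param ... named [marginal_priors] (or a single named list of them).
#' @return an object of class `pope_prior` with elements `d`, `names`,
#'   `sample()` (one joint draw), `log_density(theta)`, `support` (d x 2
#'   matrix of bounds), and `sd` (nominal per-parameter scales).
#' @export
#' @examples
#' pr <- pope_prior(theta = prior_normal(0, 1))
#' pr$log_density(0)
pope_prior <- function(...) {
  margins <- list(...)
  if (length(margins) == 1L && !inherits(margins[[1]], "pope_marginal_prior"))
    margins <- margins[[1]]
  stopifnot(length(margins) >= 1,
            all(vapply(margins, inherits, logical(1), "pope_marginal_prior")))
  nm <- names(margins)
  if (is.null(nm) || any(nm == ""))
    nm <- paste0("theta_", seq_along(margins))
  support <- t(vapply(margins, function(m) m$support, numeric(2)))
  structure(list(
    d = length(margins), names = nm, margins = margins,
    support = support,
    sd = vapply(margins, function(m) m$sd, numeric(1)),
    sample = function() vapply(margins, function(m) m$sample(1), numeric(1)),
    log_density = function(theta)
      sum(vapply(seq_along(margins),
                 function(i) margins[[i]]$logpdf(theta[i]), numeric(1)))),
    class = "pope_prior")
}

#' Custom joint prior
#'
#' Wraps an arbitrary (possibly unnormalized) log-density plus a draw
#' function into a `pope_prior`.  The draw function is used for
#' initialization by rejection; for unnormalizable kernel priors it may be
#' any distribution covering the prior's high-density region.
#'
#' @param log_density function(theta) -> scalar log-density (up to a
#'   constant), `-Inf` outside the support.
#' @param sample function() -> one draw (numeric vector of length `d`).
#' @param support `d x 2` matrix of lower/upper bounds per parameter
#'   (use `-Inf`/`Inf` for unbounded); drives the proposal transform.
#' @param names parameter names.
#' @param sd nominal per-parameter scales for default proposals.
#' @return a `pope_prior` object.
#' @export
pope_prior_custom <- function(log_density, sample, support, names = NULL,
                              sd = NULL) {
  support <- matrix(support, ncol = 2)
  d <- nrow(support)
  if (is.null(names)) names <- paste0("theta_", seq_len(d))
  if (is.null(sd)) {
    width <- support[, 2] - support[, 1]
    sd <- ifelse(is.finite(width), width / sqrt(12), 1)
  }
  structure(list(d = d, names = names, support = support, sd = sd,
                 sample = sample, log_density = log_density),
            class = "pope_prior")
}

# --- proposal transforms ----------------------------------------------------
# Random walks run in a transformed coordinate per parameter: identity on
# (-Inf, Inf), log on (0, Inf), logit on a finite interval.  The walk is
# symmetric in u-space; the theta-space proposal ratio picks up the Jacobian
# log|du/dtheta|(theta) - log|du/dtheta|(theta').

transform_kind <- function(support) {
  lo <- support[, 1]; hi <- support[, 2]
  ifelse(is.finite(lo) & is.finite(hi), 3L,        # logit
         ifelse(!is.finite(lo) & !is.finite(hi), 1L,  # identity
                2L))                                   # log (positive)
}

theta_to_u <- function(theta, support, kind) {
  u <- theta
  p <- kind == 2L
  u[p] <- log(theta[p] - support[p, 1])
  q <- kind == 3L
  if (any(q)) {
    z <- (theta[q] - support[q, 1]) / (support[q, 2] - support[q, 1])
    u[q] <- stats::qlogis(z)
  }
  u
}

u_to_theta <- function(u, support, kind) {
  theta <- u
  p <- kind == 2L
  theta[p] <- support[p, 1] + exp(u[p])
  q <- kind == 3L
  if (any(q)) {
    theta[q] <- support[q, 1] +
      (support[q, 2] - support[q, 1]) * stats::plogis(u[q])
  }
  theta
}

# log |du/dtheta| at theta, summed over parameters
log_jacobian_u <- function(theta, support, kind) {
  lj <- 0
  p <- kind == 2L
  if (any(p)) lj <- lj - sum(log(theta[p] - support[p, 1]))
  q <- kind == 3L
  if (any(q)) {
    a <- support[q, 1]; b <- support[q, 2]
    lj <- lj + sum(log(b - a) - log(theta[q] - a) - log(b - theta[q]))
  }
  lj
}
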