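#' Sampler configuration
#'
#' @param mode `"pseudo_marginal"` (the likelihood estimate of the current
#'   state is carried over between iterations; asymptotically exact, fewer
#'   simulations, can mix poorly) or `"marginal"` (the current state's
#'   likelihood is re-estimated with fresh simulations every iteration;
#'   better mixing at twice the simulation cost and a small extra
#'   approximation).
#' @param S simulations per likelihood estimate (default 1; more rarely
#'   helps).
#' @param n_iterations number of Metropolis-Hastings steps.
#' @param burnin iterations flagged as burn-in (and, when adapting, the
#'   point at which adaptation freezes); must be `< n_iterations`.
#' @param proposal_scales per-parameter random-walk standard deviations in
#'   the transformed proposal space (identity / log / logit coordinate,
#'   chosen from the prior support).  `NULL` uses 10% of the prior's
#'   nominal per-parameter standard deviation.
#' @param seed integer seed; every source of randomness in the run derives
#'   from it.
#' @param estimator `"kernel_mc"` (average of per-draw composite kernel
#'   likelihoods) or `"synthetic_gaussian"` (conditional-Gaussian CDF
#'   fitted to the `S` draws, requires `S >= 2`).
#' @return a `pope_config` object.
#' @export
pope_config <- function(mode = c("pseudo_marginal", "marginal"), S = 1,
                        n_iterations = 10000, burnin = 0,
                        proposal_scales = NULL, seed = 1,
                        estimator = c("kernel_mc", "synthetic_gaussian")) {
  mode <- match.arg(mode)
  estimator <- match.arg(estimator)
  S <- as.integer(S); n_iterations <- as.integer(n_iterations)
  burnin <- as.integer(burnin)
  stopifnot(S >= 1, n_iterations >= 0, burnin >= 0)
  if (n_iterations > 0 && burnin >= n_iterations)
    stop("`burnin` must be smaller than `n_iterations`")
  if (estimator == "synthetic_gaussian" && S < 2)
    stop("the synthetic-likelihood estimator needs S >= 2")
  if (!is.null(proposal_scales) && any(proposal_scales < 0))
    stop("proposal scales must be >= 0")
  structure(list(mode = mode, S = S, n_iterations = n_iterations,
                 burnin = burnin, proposal_scales = proposal_scales,
                 seed = as.integer(seed), estimator = estimator),
            class = "pope_config")
}

log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

# Normalize simulator output to list(y, degenerate).
eval_simulator <- function(simulator, theta) {
  out <- simulator(theta)
  if (is.list(out)) {
    list(y = as.numeric(out$y), degenerate = isTRUE(out$degenerate))
  } else {
    list(y = as.numeric(out), degenerate = FALSE)
  }
}

#' Random-walk proposal
#'
#' Component-wise Gaussian random walk in each parameter's transformed
#' coordinate: identity for unbounded parameters, log for positive ones,
#' logit for interval-bounded ones (so the proposal always respects the
#' support).  The walk is symmetric in the transformed space; the Jacobian
#' correction for the untransformed target is returned by
#' [log_proposal_ratio()].
#'
#' @param theta current parameter vector.
#' @param scales per-parameter proposal standard deviations (transformed
#'   space); zeros leave those coordinates untouched.
#' @param support `d x 2` matrix of per-parameter bounds; `NULL` means all
#'   parameters unbounded.
#' @return proposed parameter vector.
#' @export
propose <- function(theta, scales, support = NULL) {
  d <- length(theta)
  stopifnot(length(scales) == d)
  if (is.null(support)) support <- cbind(rep(-Inf, d), rep(Inf, d))
  kind <- transform_kind(support)
  u <- theta_to_u(theta, support, kind)
  u_to_theta(u + stats::rnorm(d, 0, scales), support, kind)
}

#' @rdname propose
#' @param theta_prop proposed parameter vector.
#' @return `log_proposal_ratio`: the log ratio `q(theta | theta') /
#'   q(theta' | theta)` induced by the transformed-space walk.
#' @export
log_proposal_ratio <- function(theta, theta_prop, support = NULL) {
  d <- length(theta)
  if (is.null(support)) return(0)
  kind <- transform_kind(support)
  log_jacobian_u(theta, support, kind) -
    log_jacobian_u(theta_prop, support, kind)
}

#' Estimate the (log) one-sided ABC likelihood at a parameter value
#'
#' Runs `S` simulations at `theta` and combines them per the configured
#' estimator: the log of the `S`-average of per-draw composite kernel
#' likelihoods, or the log synthetic-likelihood CDF.  Degenerate draws
#' contribute zero likelihood; if every draw is degenerate the result is
#' `-Inf`.
#'
#' @param theta parameter vector.
#' @param simulator function taking `theta` and returning a numeric
#'   statistic vector, or a list with elements `y` and `degenerate`.
#' @param specs list of [constraint_spec()] objects.
#' @param config a [pope_config()] (only `S` and `estimator` are used).
#' @return list with `log_lik`, `y_draws` (`S x J` matrix), and
#'   `degenerate` (logical vector per draw).
#' @export
estimate_log_likelihood <- function(theta, simulator, specs, config) {
  estimate_ll_tab(theta, simulator, spec_table(specs), config$S,
                  config$estimator)
}

# Internal estimator on a precomputed spec table (hot path).
estimate_ll_tab <- function(theta, simulator, tab, S, estimator) {
  draws <- NULL
  degen <- logical(S)
  ll <- numeric(S)
  for (s in seq_len(S)) {
    sim <- eval_simulator(simulator, theta)
    if (is.null(draws)) draws <- matrix(NA_real_, S, length(sim$y))
    draws[s, ] <- sim$y
    degen[s] <- sim$degenerate
    ll[s] <- if (sim$degenerate) -Inf else composite_loglik_tab(sim$y, tab)
  }
  if (estimator == "synthetic_gaussian") {
    keep <- !degen
    if (sum(keep) < 2) {
      log_lik <- -Inf
    } else {
      model <- fit_conditional_gaussian(draws[keep, , drop = FALSE])
      log_lik <- log(gaussian_cdf_tab(model, tab))
    }
  } else {
    log_lik <- log_mean_exp(ll)
  }
  list(log_lik = log_lik, y_draws = draws, degenerate = degen)
}

#' Metropolis-Hastings acceptance
#'
#' Accepts with probability `min(1, exp(log_prior_ratio + log_lik_prop -
#' log_lik_cur + log_proposal_ratio))`, evaluated entirely in log space so
#' no combination of `-Inf` and finite estimates produces `NaN`: a
#' zero-likelihood proposal is always rejected, and a finite-likelihood
#' proposal is always accepted from a zero-likelihood current state.
#'
#' @param log_lik_cur,log_lik_prop current and proposed log-likelihood
#'   estimates (possibly `-Inf`).
#' @param log_prior_ratio log prior density ratio (proposal over current).
#' @param log_proposal_ratio log proposal density ratio, see
#'   [log_proposal_ratio()].
#' @return logical: accept the proposal?
#' @export
mh_accept <- function(log_lik_cur, log_lik_prop, log_prior_ratio = 0,
                      log_proposal_ratio = 0) {
  if (log_lik_prop == -Inf || log_prior_ratio == -Inf) return(FALSE)
  if (log_lik_cur == -Inf) return(TRUE)
  log_alpha <- log_prior_ratio + log_lik_prop - log_lik_cur + log_proposal_ratio
  if (log_alpha >= 0) return(TRUE)
  log(stats::runif(1)) < log_alpha
}

#' Initialize the chain by prior rejection sampling
#'
#' Draws parameters from the prior's sampler until the estimated
#' likelihood is finite (all hard constraints satisfiable, no degeneracy).
#' Needed because a one-sided kernel chain started in an infeasible region
#' rejects every proposal and never moves.
#'
#' @inheritParams estimate_log_likelihood
#' @param prior a [pope_prior()] object.
#' @param max_tries attempts before giving up.
#' @return list with `theta`, `y_draws`, `log_lik` — a valid initial chain
#'   state.  On failure, an error naming the constraints that were violated
#'   most often.
#' @export
initialize_by_rejection <- function(prior, simulator, specs, config,
                                    max_tries = 1000) {
  stopifnot(max_tries >= 1)
  tab <- spec_table(specs)
  K <- nrow(tab)
  viol_count <- numeric(K)
  degen_count <- 0
  for (i in seq_len(max_tries)) {
    theta <- prior$sample()
    est <- estimate_ll_tab(theta, simulator, tab, config$S, config$estimator)
    if (is.finite(est$log_lik) && is.finite(prior$log_density(theta)))
      return(list(theta = theta, y_draws = est$y_draws,
                  log_lik = est$log_lik, tries = i))
    if (all(est$degenerate)) {
      degen_count <- degen_count + 1
    } else {
      y1 <- est$y_draws[which(!est$degenerate)[1], ]
      yj <- y1[tab[, "idx"]]
      v <- pmax(0, yj - tab[, "hi"], tab[, "lo"] - yj)
      viol_count <- viol_count + (v > 0)
    }
  }
  worst <- order(viol_count, decreasing = TRUE)
  msg <- if (degen_count == max_tries) {
    "every attempt produced a degenerate simulation"
  } else {
    paste0("most-violated constraints (statistic index): ",
           paste(tab[worst[seq_len(min(3, K))], "idx"], collapse = ", "))
  }
  stop("initialization failed after ", max_tries, " prior draws; ", msg)
}

#' Run POPE: one-sided kernel ABC-MCMC
#'
#' The main entry point: marginal or pseudo-marginal Metropolis-Hastings
#' over the simulator parameters, using the composite one-sided kernel
#' likelihood (or the synthetic-likelihood CDF) estimated from `S`
#' simulations per evaluation.  Optionally adapts kernel widths and
#' objective thresholds online until the end of burn-in.
#'
#' Every iteration appends one record to the trace; rejected proposals
#' duplicate the previous record, so the trace is a proper MCMC sample of
#' the joint `(theta, y)` optimization posterior / posterior predictive.
#' All simulator evaluations (including rejected proposals and marginal-
#' mode refreshes) are logged in `attr(trace, "evaluations")`, which is
#' what threshold adaptation feeds on.
#'
#' @inheritParams initialize_by_rejection
#' @param adaptation an [adapt_config()], or `NULL` for a non-adaptive run.
#' @param init an optional initial state (as returned by
#'   [initialize_by_rejection()]); by default rejection initialization is
#'   run internally.
#' @param max_init_tries attempts for the internal initialization.
#' @return a `pope_trace`: a data frame with one row per iteration
#'   (including iteration 0), columns `iteration`, `theta_*`, `y_*`
#'   (first stored draw of the current state), `log_lik`, `accepted`,
#'   `burnin`, plus `eps_<k>` and threshold snapshot columns per
#'   constraint.  Attributes: `evaluations` (all simulator calls),
#'   `acceptance_rate`, `n_simulations`, `final_eps`, `final_thresholds`,
#'   `config`.
#' @export
run_pope <- function(simulator, prior, specs, config, adaptation = NULL,
                     init = NULL, max_init_tries = 1000) {
  set.seed(config$seed)
  d <- prior$d
  support <- prior$support
  kind <- transform_kind(support)
  scales <- config$proposal_scales
  if (is.null(scales)) scales <- 0.1 * prior$sd
  if (length(scales) == 1L) scales <- rep(scales, d)
  stopifnot(length(scales) == d)

  adapting <- !is.null(adaptation)
  astate <- if (adapting) adapt_state_init(specs, adaptation) else NULL
  tab <- spec_table(specs)
  K <- nrow(tab)

  if (is.null(init))
    init <- initialize_by_rejection(prior, simulator, specs, config,
                                    max_tries = max_init_tries)
  if (!is.finite(init$log_lik))
    stop("initial state has non-finite log-likelihood")

  n <- config$n_iterations
  S <- config$S
  J <- ncol(init$y_draws)
  cur_theta <- init$theta
  cur_u <- theta_to_u(cur_theta, support, kind)
  cur_lp <- prior$log_density(cur_theta)
  cur_draws <- init$y_draws
  cur_degen <- if (is.null(init$degenerate)) rep(FALSE, nrow(cur_draws)) else
    init$degenerate
  cur_ll <- init$log_lik

  thetas <- matrix(NA_real_, n + 1, d)
  ys <- matrix(NA_real_, n + 1, J)
  loglik <- numeric(n + 1)
  accepted <- logical(n + 1)
  eps_snap <- matrix(NA_real_, n + 1, K)
  thr_snap <- matrix(NA_real_, n + 1, K)  # adaptable scalar (NA for INTERVAL)
  one_sided <- tab[, "dir"] != 3

  # evaluation log (proposals + marginal refreshes), preallocated
  max_eval <- (if (config$mode == "marginal") 2L else 1L) * n * S
  ev_theta <- matrix(NA_real_, max_eval, d)
  ev_y <- matrix(NA_real_, max_eval, J)
  ev_iter <- integer(max_eval)
  ev_role <- character(max_eval)
  ev_degen <- logical(max_eval)
  n_ev <- 0L
  n_sim <- 0L

  snapshot_thr <- function(tab) ifelse(one_sided,
                                       ifelse(tab[, "dir"] == 1, tab[, "hi"],
                                              tab[, "lo"]), NA_real_)
  # apply adaptation state onto the spec table
  apply_adapt <- function(tab, astate) {
    tab[, "eps"] <- astate$eps
    for (k in seq_len(K)) {
      thr <- astate$thresholds[[k]]
      if (tab[k, "dir"] == 1) tab[k, "hi"] <- thr
      else if (tab[k, "dir"] == 2) tab[k, "lo"] <- thr
      else { tab[k, "lo"] <- thr[1]; tab[k, "hi"] <- thr[2] }
    }
    tab
  }
  log_eval <- function(iter, theta, est, role) {
    for (s in seq_len(S)) {
      n_ev <<- n_ev + 1L
      ev_iter[n_ev] <<- iter
      ev_theta[n_ev, ] <<- theta
      ev_y[n_ev, ] <<- est$y_draws[s, ]
      ev_role[n_ev] <<- role
      ev_degen[n_ev] <<- est$degenerate[s]
    }
    n_sim <<- n_sim + S
  }
  feed_adaptation <- function(est) {
    if (!adapting || !astate$active) return(invisible())
    for (s in seq_len(S)) {
      if (est$degenerate[s]) next
      y <- est$y_draws[s, ]
      yj <- y[tab[, "idx"]]
      v <- pmax(0, yj - tab[, "hi"], tab[, "lo"] - yj)
      astate <<- update_epsilons(astate, v)
      astate <<- update_objectives(astate, y)
    }
    invisible()
  }

  record <- function(i) {
    thetas[i, ] <<- cur_theta
    ys[i, ] <<- cur_draws[1, ]
    loglik[i] <<- cur_ll
    eps_snap[i, ] <<- tab[, "eps"]
    thr_snap[i, ] <<- snapshot_thr(tab)
  }
  record(1L); accepted[1] <- NA

  for (i in seq_len(n)) {
    if (adapting && astate$active && i > config$burnin)
      astate <- freeze(astate)
    if (adapting) {
      new_tab <- apply_adapt(tab, astate)
      if (!identical(new_tab, tab)) {
        tab <- new_tab
        # the carried pseudo-marginal estimate must match the current
        # specs; in marginal mode the refresh below re-estimates anyway
        if (config$mode != "marginal") {
          if (config$estimator == "synthetic_gaussian") {
            keep <- !cur_degen
            cur_ll <- if (sum(keep) < 2) -Inf else
              log(gaussian_cdf_tab(
                fit_conditional_gaussian(cur_draws[keep, , drop = FALSE]),
                tab))
          } else {
            ll <- apply(cur_draws, 1, composite_loglik_tab, tab = tab)
            ll[cur_degen] <- -Inf
            cur_ll <- log_mean_exp(ll)
          }
        }
      }
    }
    if (config$mode == "marginal") {
      est_cur <- estimate_ll_tab(cur_theta, simulator, tab, S,
                                 config$estimator)
      log_eval(i, cur_theta, est_cur, "current")
      feed_adaptation(est_cur)
      # The refreshed draws are an unconditioned sample of p(y | theta) at
      # the current state; storing them on the current state's record (the
      # proposal draw that produced an accepted state is conditioned on
      # satisfying the constraints) keeps the recorded posterior
      # predictive unbiased.
      cur_draws <- est_cur$y_draws
      cur_degen <- est_cur$degenerate
      ys[i, ] <- cur_draws[1, ]
      # Denominator guard: a zero refreshed estimate at a state whose
      # carried estimate is positive is estimator noise, not evidence of
      # infeasibility; adopting it would make the acceptance ratio
      # prior-blind (x/0) and measurably bias the chain.  Keeping the last
      # positive estimate reduces, for indicator kernels, to standard
      # ABC-MCMC, which is exact.
      if (is.finite(est_cur$log_lik) || !is.finite(cur_ll)) {
        cur_ll <- est_cur$log_lik
      }
    }
    u_prop <- cur_u + stats::rnorm(d, 0, scales)
    theta_prop <- u_to_theta(u_prop, support, kind)
    lp_prop <- prior$log_density(theta_prop)
    est_prop <- estimate_ll_tab(theta_prop, simulator, tab, S,
                                config$estimator)
    log_eval(i, theta_prop, est_prop, "proposal")
    feed_adaptation(est_prop)
    lqr <- log_jacobian_u(cur_theta, support, kind) -
      log_jacobian_u(theta_prop, support, kind)
    acc <- mh_accept(cur_ll, est_prop$log_lik, lp_prop - cur_lp, lqr)
    if (acc) {
      cur_theta <- theta_prop; cur_u <- u_prop; cur_lp <- lp_prop
      cur_draws <- est_prop$y_draws; cur_degen <- est_prop$degenerate
      cur_ll <- est_prop$log_lik
    }
    accepted[i + 1L] <- acc
    record(i + 1L)
  }

  trace <- data.frame(iteration = 0:n)
  colnames(thetas) <- prior$names
  colnames(ys) <- paste0("y_", seq_len(J))
  trace <- cbind(trace, thetas, ys)
  trace$log_lik <- loglik
  trace$accepted <- accepted
  trace$burnin <- trace$iteration <= config$burnin
  colnames(eps_snap) <- paste0("eps_", seq_len(K))
  colnames(thr_snap) <- paste0("thr_", seq_len(K))
  trace <- cbind(trace, eps_snap, thr_snap)
  class(trace) <- c("pope_trace", "data.frame")

  ev <- data.frame(iteration = ev_iter[seq_len(n_ev)],
                   role = ev_role[seq_len(n_ev)])
  colnames(ev_theta) <- prior$names
  colnames(ev_y) <- paste0("y_", seq_len(J))
  ev <- cbind(ev, ev_theta[seq_len(n_ev), , drop = FALSE],
              ev_y[seq_len(n_ev), , drop = FALSE])
  ev$degenerate <- ev_degen[seq_len(n_ev)]

  attr(trace, "evaluations") <- ev
  attr(trace, "acceptance_rate") <- if (n > 0) mean(accepted[-1]) else NA_real_
  attr(trace, "n_simulations") <- n_sim
  attr(trace, "init_tries") <- init$tries
  attr(trace, "final_eps") <- tab[, "eps"]
  attr(trace, "final_thresholds") <- if (adapting) astate$thresholds else
    lapply(specs, function(s) s$threshold)
  attr(trace, "config") <- config
  trace
}

#' @export
print.pope_trace <- function(x, ...) {
  n <- nrow(x) - 1L
  cat(sprintf("<pope_trace> %d iterations (+initial), acceptance %.1f%%, %d simulations\n",
              n, 100 * attr(x, "acceptance_rate"), attr(x, "n_simulations")))
  invisible(x)
}
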