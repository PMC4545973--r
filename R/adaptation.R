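#' Adaptation configuration
#'
#' Controls the online adaptation of kernel widths (epsilon) and of unknown
#' objective thresholds during the MCMC run.  Epsilon is set to a quantile
#' of an exponential moving average (EMA) of the constraint discrepancies,
#' floored at each constraint's `epsilon_min`; a small quantile `beta`
#' keeps pressure on the chain to shrink epsilon.  Objective thresholds are
#' updated to the best value seen (deterministic simulators) or to the
#' running minimum of an EMA of the objective statistic (stochastic
#' simulators), so an improvement must be consistently better before the
#' threshold moves.  Adaptation is frozen at the end of burn-in, after
#' which the chain is plain non-adaptive ABC-MCMC.
#'
#' @param beta quantile in (0, 1) of the EMA window used for epsilon.
#' @param delta EMA decay for discrepancies, in (0, 1]; `delta = 1` freezes
#'   the EMA.
#' @param gamma EMA decay for the objective statistic, in (0, 1].
#' @param window number of EMA snapshots retained for the quantile.
#' @param adapt_epsilon,adapt_objective switch the two mechanisms on/off.
#' @param deterministic logical; the simulator is deterministic, so the
#'   objective threshold can be updated from raw values rather than the EMA.
#' @param ramp optional number of updates over which `delta` and `gamma`
#'   ramp linearly to 1 (an alternative to the hard freeze); `NULL` (the
#'   default) disables the ramp.
#' @return an `adapt_config` object.
#' @export
adapt_config <- function(beta = 0.2, delta = 0.9, gamma = 0.9, window = 500,
                         adapt_epsilon = TRUE, adapt_objective = FALSE,
                         deterministic = FALSE, ramp = NULL) {
  stopifnot(beta > 0, beta < 1, delta > 0, delta <= 1, gamma > 0, gamma <= 1,
            window >= 1)
  structure(list(beta = beta, delta = delta, gamma = gamma,
                 window = as.integer(window),
                 adapt_epsilon = isTRUE(adapt_epsilon),
                 adapt_objective = isTRUE(adapt_objective),
                 deterministic = isTRUE(deterministic), ramp = ramp),
            class = "adapt_config")
}

#' Initialize adaptation state
#'
#' @param specs list of [constraint_spec()] objects; their `epsilon`,
#'   `epsilon_min`, thresholds, and `objective` flags seed the state.
#' @param config an [adapt_config()].
#' @return an `adapt_state` object carrying the current epsilon vector,
#'   current thresholds, EMA accumulators, the rolling discrepancy window,
#'   and the `active` flag.
#' @export
adapt_state_init <- function(specs, config = adapt_config()) {
  K <- length(specs)
  structure(list(
    config = config,
    eps = vapply(specs, function(s) s$epsilon, numeric(1)),
    eps_min = vapply(specs, function(s) s$epsilon_min, numeric(1)),
    thresholds = lapply(specs, function(s) s$threshold),
    stat_idx = vapply(specs, function(s) s$statistic, integer(1)),
    directions = vapply(specs, function(s) s$direction, character(1)),
    objective = vapply(specs, function(s) s$objective, logical(1)),
    ema_d = rep(NA_real_, K),
    window = matrix(NA_real_, nrow = config$window, ncol = K),
    w_count = 0L,
    ema_y = rep(NA_real_, K),
    n_updates = 0L,
    active = TRUE), class = "adapt_state")
}

# Effective decay with the optional linear ramp toward 1.
effective_decay <- function(base, ramp, step) {
  if (is.null(ramp)) return(base)
  base + (1 - base) * min(1, step / ramp)
}

#' Update kernel widths from constraint discrepancies
#'
#' Feeds one vector of per-constraint violation magnitudes into the EMA,
#' pushes the EMA snapshot into the rolling window, and resets each epsilon
#' to the `beta`-quantile of its window, floored at `epsilon_min`.  A no-op
#' once the state is frozen or when epsilon adaptation is disabled.
#'
#' @param state an [adapt_state_init()] state.
#' @param discrepancies numeric vector of violation magnitudes (one per
#'   constraint, `>= 0`).
#' @return the updated state (functional update; reassign it).
#' @export
update_epsilons <- function(state, discrepancies) {
  if (!state$active || !state$config$adapt_epsilon) return(state)
  cfg <- state$config
  state$n_updates <- state$n_updates + 1L
  delta <- effective_decay(cfg$delta, cfg$ramp, state$n_updates)
  state$ema_d <- ifelse(is.na(state$ema_d), discrepancies,
                        delta * state$ema_d + (1 - delta) * discrepancies)
  slot <- ((state$w_count) %% cfg$window) + 1L
  state$window[slot, ] <- state$ema_d
  state$w_count <- state$w_count + 1L
  filled <- seq_len(min(state$w_count, cfg$window))
  q <- apply(state$window[filled, , drop = FALSE], 2, stats::quantile,
             probs = cfg$beta, names = FALSE)
  state$eps <- pmax(q, state$eps_min)
  state
}

#' Update objective thresholds from a simulated statistic vector
#'
#' For each constraint marked as an objective: a deterministic simulator
#' updates the threshold to the best raw value seen (minimum for LE,
#' maximum for GE); a stochastic one updates an EMA of the statistic and
#' moves the threshold only when the EMA beats it, so the threshold is a
#' local average and never worsens.  A no-op when frozen or disabled.
#'
#' @param state an adaptation state.
#' @param y simulator statistic vector.
#' @param deterministic overrides the config's `deterministic` flag when
#'   not `NULL`.
#' @return the updated state.
#' @export
update_objectives <- function(state, y, deterministic = NULL) {
  if (!state$active || !state$config$adapt_objective) return(state)
  det <- if (is.null(deterministic)) state$config$deterministic else deterministic
  gam <- effective_decay(state$config$gamma, state$config$ramp, state$n_updates)
  for (k in which(state$objective)) {
    yv <- y[[state$stat_idx[k]]]
    if (det) {
      cand <- yv
    } else {
      # the local average starts at the incumbent objective estimate when
      # one exists, so gamma = 1 leaves the threshold untouched
      if (is.na(state$ema_y[k])) {
        thr0 <- state$thresholds[[k]][1]
        state$ema_y[k] <- if (is.finite(thr0)) thr0 else yv
      }
      state$ema_y[k] <- gam * state$ema_y[k] + (1 - gam) * yv
      cand <- state$ema_y[k]
    }
    if (state$directions[k] == "LE") {
      state$thresholds[[k]] <- min(state$thresholds[[k]], cand)
    } else if (state$directions[k] == "GE") {
      state$thresholds[[k]] <- max(state$thresholds[[k]], cand)
    }
  }
  state
}

#' Freeze adaptation
#'
#' Marks the state inactive; all subsequent updates are no-ops, so epsilon
#' and the thresholds stay at their current values (the post burn-in,
#' non-adaptive regime).  Idempotent.
#'
#' @param state an adaptation state.
#' @return the frozen state.
#' @export
freeze <- function(state) {
  state$active <- FALSE
  state
}
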