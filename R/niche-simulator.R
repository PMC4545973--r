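#' Stem-cell niche geometry
#'
#' The niche is a closed-ended tube of `D` cell rows; row `d` holds up to
#' `theta_d` cells.  To enforce monotonically non-decreasing row sizes the
#' geometry is parameterized by non-negative increments `g`:
#' `theta_1 = 1 + g_1`, `theta_d = theta_{d-1} + g_d`.  Integer row
#' capacities are the row sizes rounded half-up, floored at one cell.
#'
#' @param g numeric vector of `D` non-negative increments.
#' @return a `niche_geometry` with elements `g`, `theta`, `capacity`, `D`.
#' @export
#' @examples
#' geometry_from_increments(c(1, 2, 3))$theta  # 2 4 7
geometry_from_increments <- function(g) {
  if (any(g < 0)) stop("niche increments must satisfy g_d >= 0")
  theta <- 1 + cumsum(g)
  structure(list(g = as.numeric(g), theta = theta,
                 capacity = pmax(1L, as.integer(floor(theta + 0.5))),
                 D = length(g)),
            class = "niche_geometry")
}

#' @export
print.niche_geometry <- function(x, ...) {
  cat("<niche geometry> rows:", paste(round(x$theta, 2), collapse = " "),
      "| capacity", sum(x$capacity), "cells\n")
  invisible(x)
}

#' Soft-kernel prior specification for niche geometries
#'
#' Three groups of one-sided Gaussian constraints keep geometries
#' realistic: the first row size (through `g_1 <= tau_g1`), the
#' increments (`g_d <= tau_gd`, "well-behaved", no large jumps), and the
#' total niche size (`sum(theta) <= tau_theta`).  The hard constraint
#' `g_d >= 0` is enforced separately by [geometry_from_increments()].
#'
#' @param tau_g1 threshold on the first increment (399 leaves the first
#'   row free over 1..400).
#' @param tau_gd threshold on later increments (10 for well-behaved
#'   geometries, 399 to effectively remove the constraint).
#' @param tau_theta threshold on total niche size (400 or 1500).
#' @param eps_g1,eps_gd,eps_theta kernel widths of the three groups.
#' @return a `niche_prior_spec` object.
#' @export
niche_prior_spec <- function(tau_g1 = 399, tau_gd = 10, tau_theta = 400,
                             eps_g1 = 0.1, eps_gd = 0.1, eps_theta = 1) {
  stopifnot(tau_g1 > 0, tau_gd > 0, tau_theta > 0,
            eps_g1 > 0, eps_gd > 0, eps_theta > 0)
  structure(list(tau_g1 = tau_g1, tau_gd = tau_gd, tau_theta = tau_theta,
                 eps_g1 = eps_g1, eps_gd = eps_gd, eps_theta = eps_theta),
            class = "niche_prior_spec")
}

#' Log prior density of a niche increment vector
#'
#' Product of the one-sided Gaussian kernels of [niche_prior_spec()]
#' evaluated in log space; `-Inf` for any negative increment.
#'
#' @param g increment vector.
#' @param prior_spec a [niche_prior_spec()].
#' @return unnormalized log prior `<= 0`.
#' @export
niche_log_prior <- function(g, prior_spec) {
  if (any(g < 0)) return(-Inf)
  geo <- geometry_from_increments(g)
  k1 <- constraint_spec(1, "LE", prior_spec$tau_g1,
                        kernel = "gaussian_one_sided",
                        epsilon = prior_spec$eps_g1)
  kd <- constraint_spec(1, "LE", prior_spec$tau_gd,
                        kernel = "gaussian_one_sided",
                        epsilon = prior_spec$eps_gd)
  kt <- constraint_spec(1, "LE", prior_spec$tau_theta,
                        kernel = "gaussian_one_sided",
                        epsilon = prior_spec$eps_theta)
  log_kernel(g[1], k1) +
    sum(vapply(g[-1], log_kernel, numeric(1), spec = kd)) +
    log_kernel(sum(geo$theta), kt)
}

#' Joint prior object over niche increments
#'
#' Wraps [niche_log_prior()] for [run_pope()].  The prior is an
#' unnormalized soft-kernel density, so the draw function (used only for
#' initialization by rejection) samples increments uniformly inside the
#' kernel thresholds, which covers the prior's plateau of density one.
#'
#' @param prior_spec a [niche_prior_spec()].
#' @param D number of rows.
#' @return a [pope_prior_custom()] object over `g`.
#' @export
niche_prior <- function(prior_spec = niche_prior_spec(), D = 8) {
  caps <- c(prior_spec$tau_g1, rep(prior_spec$tau_gd, D - 1))
  pope_prior_custom(
    log_density = function(g) niche_log_prior(g, prior_spec),
    sample = function() stats::runif(D, 0, caps),
    support = cbind(rep(0, D), rep(Inf, D)),
    names = paste0("g_", seq_len(D)),
    sd = rep(1, D))
}

#' Simulate the stem-cell niche
#'
#' Event-driven (Gillespie) simulation of cell cycling in the niche tube.
#' Every cell divides after an independent exponential waiting time (rate
#' one per cell, which fixes the time unit as the mean cell-cycle time).
#' The daughter is placed in the mother's row; if that row and every row
#' toward the open end are full, the chain displacement pushes a cell out
#' of row `D`, which leaves the cycle and differentiates.  The niche
#' starts full (its steady operating state), so it remains full and every
#' division exports one differentiated cell; the spatial bookkeeping
#' still tracks per-row occupancy against capacity.  The simulation
#' returns the time at which the `n_target`-th differentiated cell is
#' produced.
#'
#' @param geometry a [geometry_from_increments()] result.
#' @param n_target number of differentiated cells to produce.
#' @param seed optional integer seed (otherwise the current RNG stream is
#'   used).
#' @param detail logical; also return event-level bookkeeping (per-row
#'   maximum occupancy, event count) for invariant checks.
#' @return the simulated time (scalar), or a list when `detail = TRUE`.
#' @export
simulate_niche <- function(geometry, n_target = 300, seed = NULL,
                           detail = FALSE) {
  stopifnot(inherits(geometry, "niche_geometry"), n_target >= 0)
  if (!is.null(seed)) set.seed(seed)
  cap <- geometry$capacity
  D <- geometry$D
  occ <- cap  # start at the full steady state
  n_cells <- sum(occ)
  stopifnot(n_cells >= 1)
  if (n_target == 0) {
    if (detail) return(list(time = 0, max_occ = occ, n_events = 0L))
    return(0)
  }
  t <- 0
  produced <- 0L
  max_occ <- occ
  n_events <- 0L
  while (produced < n_target) {
    t <- t + stats::rexp(1, rate = n_cells)
    row <- sample.int(D, 1L, prob = occ)
    # chain displacement: daughter enters `row`; first free slot at or
    # beyond it absorbs the push, otherwise a cell exits and differentiates
    free <- which(occ[row:D] < cap[row:D])
    if (length(free) > 0) {
      occ[row + free[1] - 1L] <- occ[row + free[1] - 1L] + 1L
      n_cells <- n_cells + 1L
    } else {
      produced <- produced + 1L
    }
    n_events <- n_events + 1L
    max_occ <- pmax(max_occ, occ)
  }
  if (detail) list(time = t, max_occ = max_occ, n_events = n_events)
  else t
}

#' Replicate-averaged niche statistic
#'
#' Repeats [simulate_niche()] `M` times at the same geometry and returns
#' the mean time; the variance of the averaged statistic shrinks as
#' `1/M`.
#'
#' @inheritParams simulate_niche
#' @param M number of replicates.
#' @return mean simulated time over `M` replicates.
#' @export
replicate_average <- function(geometry, M, n_target = 300, seed = NULL) {
  if (M < 1) stop("`M` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  mean(vapply(seq_len(M), function(m)
    simulate_niche(geometry, n_target = n_target), numeric(1)))
}

#' Niche simulator closure for the sampler
#'
#' @param n_target differentiated-cell target (the statistic is the time
#'   to reach it).
#' @param M replicates averaged into the statistic.
#' @return function mapping an increment vector `g` to the scalar
#'   statistic, conforming to the [run_pope()] simulator contract.
#' @export
niche_simulator <- function(n_target = 300, M = 1) {
  force(n_target); force(M)
  function(g) {
    geo <- geometry_from_increments(g)
    replicate_average(geo, M = M, n_target = n_target)
  }
}

#' Row-size frequency table of a niche posterior
#'
#' Tabulates, per row, the posterior frequency of each integer row size in
#' the retained trace records — the numbers behind bubble-style geometry
#' plots.
#'
#' @param trace a `pope_trace` from a niche run (parameter columns
#'   `g_1..g_D`).
#' @param retained logical; drop burn-in records first.
#' @return data frame with columns `row`, `size`, `frequency`.
#' @export
niche_row_frequencies <- function(trace, retained = TRUE) {
  df <- if (retained) trace[!trace$burnin, , drop = FALSE] else trace
  gcols <- grep("^g_", colnames(df), value = TRUE)
  if (length(gcols) == 0) stop("trace has no increment columns g_*")
  out <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    geo <- geometry_from_increments(as.numeric(df[i, gcols]))
    data.frame(row = seq_len(geo$D), size = geo$capacity)
  }))
  agg <- stats::aggregate(list(count = out$row),
                          by = list(row = out$row, size = out$size), length)
  agg$frequency <- agg$count / nrow(df)
  agg[order(agg$row, agg$size), c("row", "size", "frequency")]
}
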