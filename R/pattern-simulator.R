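#' Gierer-Meinhardt simulator parameters
#'
#' Parameters of the one-dimensional Wnt activator / Wnt-inhibitor
#' reaction-diffusion model of tumor spotting patterns.  Wnt (`W`) is the
#' activator: it autocatalyses its own production, which is damped by the
#' inhibitor (`W_I`) that Wnt itself induces — the classic
#' Gierer-Meinhardt mechanism.  The implemented reaction terms are
#'
#' \deqn{\partial W/\partial t   = \kappa_W W^2/(a + b W_I) - \mu_W W + S_W + D_W \partial^2 W/\partial x^2}
#' \deqn{\partial W_I/\partial t = \kappa_{WI} W^2 - \mu_{WI} W_I + D_{WI} \partial^2 W_I/\partial x^2}
#'
#' a reconstruction of the published parameter roles (the governing
#' equations themselves are not public); the reaction terms can be swapped
#' via the `reactions` hook of [simulate_gm_1d()].  Spots form in the
#' Turing regime, i.e. when the inhibitor diffuses much faster than the
#' activator.
#'
#' @param kappa_W rate of nonlinear Wnt production (> 0).
#' @param kappa_WI rate of Wnt-inhibitor production (> 0).
#' @param mu_W,mu_WI decay rates of Wnt and its inhibitor (>= 0).
#' @param a,b constants of inhibition (`a` baseline, `b` weight of the
#'   inhibitor), both >= 0.
#' @param S_W rate of constitutive Wnt production (>= 0).
#' @param D_W diffusion coefficient of Wnt, in (0, 1].
#' @param N nutrient level, in (0, 1]; scales the glycolytic cell
#'   fraction.
#' @return a `gm_params` object.
#' @export
gm_params <- function(kappa_W, kappa_WI, mu_W, mu_WI, a, b, S_W, D_W, N) {
  # inference uses kappa_W, kappa_WI > 0; zero is allowed here so the
  # linear-dynamics limit of the model can be exercised directly
  stopifnot(kappa_W >= 0, kappa_WI >= 0, mu_W >= 0, mu_WI >= 0, a >= 0,
            b >= 0, S_W >= 0, D_W > 0, D_W <= 1, N > 0, N <= 1)
  structure(list(kappa_W = kappa_W, kappa_WI = kappa_WI, mu_W = mu_W,
                 mu_WI = mu_WI, a = a, b = b, S_W = S_W, D_W = D_W, N = N),
            class = "gm_params")
}

#' @rdname gm_params
#' @details `gm_mock_params()` returns the parameter setting whose
#'   simulated patterns match Mock (untreated) tumor tissue; its
#'   statistics define the constraint thresholds of
#'   [mock_constraint_specs()].
#' @export
gm_mock_params <- function() {
  gm_params(kappa_W = 40.44, kappa_WI = 127.4, mu_W = 20.64, mu_WI = 42.36,
            a = 1e-8, b = 1, S_W = 1, D_W = 0.01, N = 1)
}

as_gm_params <- function(theta) {
  if (inherits(theta, "gm_params")) return(theta)
  stopifnot(length(theta) == 9)
  do.call(gm_params, as.list(as.numeric(theta)))
}

#' Homogeneous steady state of the reaction terms
#'
#' Solves the spatially homogeneous fixed point of the implemented
#' activator-inhibitor system: `W_I0 = kappa_WI W0^2 / mu_WI` and the
#' scalar root of the Wnt balance equation, found by bracketed
#' root-finding and polished so both residuals are below `1e-10`.
#'
#' @param params a [gm_params()] object.
#' @return list with `W0` and `WI0` (non-negative).
#' @export
gm_steady_state <- function(params) {
  p <- params
  stopifnot(p$mu_W > 0, p$mu_WI > 0)
  if (p$kappa_W == 0)
    return(list(W0 = p$S_W / p$mu_W,
                WI0 = p$kappa_WI * (p$S_W / p$mu_W)^2 / p$mu_WI))
  if (p$b == 0 && p$a == 0) stop("degenerate inhibition constants")
  h <- function(W) {
    WI <- p$kappa_WI * W^2 / p$mu_WI
    p$kappa_W * W^2 / (p$a + p$b * WI) - p$mu_W * W + p$S_W
  }
  lo <- 0
  if (p$S_W == 0) {
    # W = 0 is always a root; prefer the positive root when one exists
    cand <- 10^seq(-8, 4, by = 0.25)
    pos <- cand[vapply(cand, h, numeric(1)) > 0]
    if (length(pos) == 0) return(list(W0 = 0, WI0 = 0))
    lo <- pos[1]
  }
  hi <- max(1, lo, 2 * p$S_W / p$mu_W)
  tries <- 0
  while (h(hi) > 0 && tries < 200) { hi <- hi * 2; tries <- tries + 1 }
  if (h(hi) > 0) stop("no non-negative homogeneous steady state found")
  W0 <- stats::uniroot(h, c(lo, hi), tol = .Machine$double.eps^0.8)$root
  # Newton polish for the residual tolerance
  for (i in 1:5) {
    eps <- max(1e-9, abs(W0) * 1e-9)
    dh <- (h(W0 + eps) - h(W0 - eps)) / (2 * eps)
    if (dh != 0) W0 <- W0 - h(W0) / dh
  }
  list(W0 = W0, WI0 = p$kappa_WI * W0^2 / p$mu_WI)
}

#' Grid and integration settings for the 1D simulator
#'
#' @param n_x grid points on the domain.
#' @param length domain length (no-flux boundaries at both ends).
#' @param dt time step of the default semi-implicit integrator (implicit
#'   diffusion, explicit reaction); the explicit reference integrator
#'   instead uses `dt_explicit` (or, when `NULL`, 40% of its diffusion
#'   stability bound).
#' @param t_final integration horizon; the default is long enough for the
#'   pattern to reach its (discrete) steady state, at which point the
#'   profile no longer depends on the integrator.
#' @param D_WI inhibitor diffusion coefficient; `NULL` means `50 * D_W`
#'   (well inside the Turing regime).
#' @param noise relative amplitude of the seeded perturbation of the
#'   homogeneous initial state.
#' @param seed integer seed for the initial perturbation.
#' @param dt_explicit optional explicit-Euler step.
#' @return a `gm_grid` object.
#' @export
gm_grid <- function(n_x = 256, length = 1, dt = 5e-4, t_final = 8,
                    D_WI = NULL, noise = 0.01, seed = 1,
                    dt_explicit = NULL) {
  stopifnot(n_x >= 8, length > 0, dt > 0, t_final > 0, noise >= 0)
  structure(list(n_x = as.integer(n_x), length = length, dt = dt,
                 t_final = t_final, D_WI = D_WI, noise = noise,
                 seed = as.integer(seed), dt_explicit = dt_explicit),
            class = "gm_grid")
}

# Dense Cholesky factor of (I - dt * D * L) with no-flux Laplacian.
implicit_factor <- function(n, dx, dt, D) {
  r <- dt * D / dx^2
  A <- diag(1 + 2 * r, n)
  A[cbind(1:(n - 1), 2:n)] <- -r
  A[cbind(2:n, 1:(n - 1))] <- -r
  A[1, 1] <- 1 + r
  A[n, n] <- 1 + r
  chol(A)
}

neumann_laplacian <- function(v, dx) {
  n <- length(v)
  (c(v[1], v[-n]) - 2 * v + c(v[-1], v[n])) / dx^2
}

default_reactions <- function(p) {
  function(W, WI) {
    list(dW = p$kappa_W * W^2 / (p$a + p$b * WI) - p$mu_W * W + p$S_W,
         dWI = p$kappa_WI * W^2 - p$mu_WI * WI)
  }
}

#' Integrate the 1D activator-inhibitor model
#'
#' Integrates the reaction-diffusion pair from the homogeneous steady
#' state perturbed by small seeded noise, with no-flux boundaries.  The
#' default scheme treats diffusion implicitly and the reactions
#' explicitly; `method = "explicit"` is a plain explicit-Euler reference
#' on a fine time grid.  Both schemes share the spatial discretization,
#' so a fully converged pattern is integrator-independent.  The glycolytic
#' fraction is derived from Wnt as
#' `P_g = N * plogis(-(W - median(W)) / s)` (Wnt suppresses glycolytic
#' activity), with `s` a smoothing scale of 10% of the Wnt dynamic range,
#' and `P_o = 1 - P_g`.
#'
#' @param params a [gm_params()] object (or the length-9 numeric vector).
#' @param grid a [gm_grid()] object.
#' @param method `"semi_implicit"` (default) or `"explicit"`.
#' @param reactions optional hook: `function(params)` returning
#'   `function(W, WI) -> list(dW, dWI)`, replacing the built-in reaction
#'   terms.
#' @param smoothing smoothing scale `s` of the glycolytic response, as a
#'   fraction of the Wnt dynamic range.
#' @return a `gm_profile` data frame with columns `x`, `W`, `W_I`, `P_o`,
#'   `P_g`; attribute `y2_stable` records whether the spot count was
#'   unchanged over the last 20% of the integration.
#' @export
simulate_gm_1d <- function(params, grid = gm_grid(),
                           method = c("semi_implicit", "explicit"),
                           reactions = NULL, smoothing = 0.1) {
  p <- as_gm_params(params)
  method <- match.arg(method)
  D_WI <- if (is.null(grid$D_WI)) 50 * p$D_W else grid$D_WI
  n <- grid$n_x
  dx <- grid$length / (n - 1)
  react <- if (is.null(reactions)) default_reactions(p) else reactions(p)

  ss <- gm_steady_state(p)
  set.seed(grid$seed)
  W <- ss$W0 * (1 + grid$noise * stats::rnorm(n))
  WI <- ss$WI0 * (1 + grid$noise * stats::rnorm(n))
  W <- pmax(W, 0); WI <- pmax(WI, 0)

  dt <- if (method == "explicit") {
    if (!is.null(grid$dt_explicit)) grid$dt_explicit else
      0.4 * dx^2 / max(D_WI, p$D_W)
  } else grid$dt
  n_steps <- ceiling(grid$t_final / dt)
  check_at <- max(1L, floor(0.8 * n_steps))
  W_check <- NULL

  if (method == "semi_implicit") {
    RW <- implicit_factor(n, dx, dt, p$D_W)
    RI <- implicit_factor(n, dx, dt, D_WI)
  }
  for (step in seq_len(n_steps)) {
    r <- react(W, WI)
    if (method == "semi_implicit") {
      W <- backsolve(RW, forwardsolve(t(RW), W + dt * r$dW))
      WI <- backsolve(RI, forwardsolve(t(RI), WI + dt * r$dWI))
    } else {
      W <- W + dt * (r$dW + p$D_W * neumann_laplacian(W, dx))
      WI <- WI + dt * (r$dWI + D_WI * neumann_laplacian(WI, dx))
    }
    if (!all(is.finite(W)) || !all(is.finite(WI)))
      stop("integration blew up at step ", step,
           " (t = ", format(step * dt), "); reduce dt")
    if (step == check_at) W_check <- W
  }

  profile <- gm_profile(W, WI, p, dx, smoothing)
  if (!is.null(W_check)) {
    prof80 <- gm_profile(W_check, WI, p, dx, smoothing)
    attr(profile, "y2_stable") <-
      compute_spot_statistics(profile)$y[2] ==
      compute_spot_statistics(prof80)$y[2]
  }
  profile
}

# Assemble the output profile: cell fractions from the Wnt field.
gm_profile <- function(W, WI, p, dx, smoothing = 0.1) {
  rng <- max(W) - min(W)
  s <- max(smoothing * rng, 1e-8)
  P_g <- p$N * stats::plogis(-(W - stats::median(W)) / s)
  out <- data.frame(x = (seq_along(W) - 1) * dx, W = W, W_I = WI,
                    P_o = 1 - P_g, P_g = P_g)
  class(out) <- c("gm_profile", "data.frame")
  out
}

#' Spot statistics of a 1D pattern
#'
#' Detects spots as maximal runs of grid points where the glycolytic
#' fraction exceeds the mid-level between its minimum and maximum, with a
#' minimum run length (default 2 points) to suppress single-point noise.
#' The four statistics are: `y1` the average spot width (mean run length
#' times the grid spacing), `y2` the number of spots, `y3` the average
#' background level (mean `P_g` outside spots), and `y4` the average Wnt
#' level.  A pattern with no spots, or with a glycolytic dynamic range
#' below `range_floor`, is degenerate and receives zero likelihood.
#'
#' @param profile a `gm_profile` (or any data frame with columns `x`,
#'   `W`, `P_g`).
#' @param min_run minimum spot length in grid points.
#' @param range_floor minimum `P_g` dynamic range for a non-degenerate
#'   pattern.
#' @return a `spot_statistics` list: `y = c(y1, y2, y3, y4)` and
#'   `degenerate`.
#' @export
compute_spot_statistics <- function(profile, min_run = 2,
                                    range_floor = 1e-4) {
  stopifnot(all(c("x", "W", "P_g") %in% colnames(profile)))
  pg <- profile$P_g
  stopifnot(all(is.finite(pg)), all(is.finite(profile$W)))
  dx <- profile$x[2] - profile$x[1]
  rng <- max(pg) - min(pg)
  if (rng < range_floor) {
    return(structure(list(y = c(NA_real_, 0, mean(pg), mean(profile$W)),
                          degenerate = TRUE), class = "spot_statistics"))
  }
  thr <- (max(pg) + min(pg)) / 2
  runs <- rle(pg > thr)
  spot <- runs$values & runs$lengths >= min_run
  n_spots <- sum(spot)
  if (n_spots == 0) {
    return(structure(list(y = c(NA_real_, 0, mean(pg), mean(profile$W)),
                          degenerate = TRUE), class = "spot_statistics"))
  }
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  in_spot <- rep(FALSE, length(pg))
  for (i in which(spot)) in_spot[starts[i]:ends[i]] <- TRUE
  structure(list(
    y = c(mean(runs$lengths[spot]) * dx, n_spots,
          mean(pg[!in_spot]), mean(profile$W)),
    degenerate = FALSE), class = "spot_statistics")
}

#' @export
print.spot_statistics <- function(x, ...) {
  cat(sprintf("<spot statistics> width=%.3g, spots=%d, background=%.3g, Wnt=%.3g%s\n",
              x$y[1], x$y[2], x$y[3], x$y[4],
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Mock constraint specification
#'
#' The constraints that define "patterns different from Mock tissue": spot
#' width above the Mock width 0.604, spot count in 2..4 (fewer than the
#' Mock's 5, at least 2 for a genuine pattern), background below the Mock
#' 0.807, and average Wnt below the Mock 5.67.  One-sided Gaussian
#' kernels with widths (0.01, 0.05, 0.01, 0.05); `eps_scale = 10` gives
#' the loose variant (0.1, 0.5, 0.1, 0.5).
#'
#' @param eps_scale multiplier on the default kernel widths.
#' @return list of four [constraint_spec()] objects.
#' @export
mock_constraint_specs <- function(eps_scale = 1) {
  eps <- c(0.01, 0.05, 0.01, 0.05) * eps_scale
  list(constraint_spec(1, "GE", 0.604, kernel = "gaussian_one_sided",
                       epsilon = eps[1]),
       constraint_spec(2, "INTERVAL", c(2, 4), kernel = "gaussian_one_sided",
                       epsilon = eps[2]),
       constraint_spec(3, "LE", 0.807, kernel = "gaussian_one_sided",
                       epsilon = eps[3]),
       constraint_spec(4, "LE", 5.67, kernel = "gaussian_one_sided",
                       epsilon = eps[4]))
}

#' Pattern simulator closure for the sampler
#'
#' @param grid a [gm_grid()] object shared by all evaluations.
#' @param ... passed to [simulate_gm_1d()].
#' @return function mapping the 9-vector of [gm_params()] values to
#'   `list(y, degenerate)` per the [run_pope()] simulator contract.
#' @export
pattern_simulator <- function(grid = gm_grid(), ...) {
  force(grid)
  function(theta) {
    profile <- simulate_gm_1d(theta, grid = grid, ...)
    st <- compute_spot_statistics(profile)
    y <- st$y
    if (st$degenerate) y[is.na(y)] <- 0
    list(y = y, degenerate = st$degenerate)
  }
}

#' Diffuse prior over the pattern-simulator parameters
#'
#' Log-normal priors on the seven rate/inhibition parameters, centered at
#' the Mock setting with a wide spread (sdlog 1.5, about three decades of
#' central mass), and weak Beta(2, 2) priors on the unit-interval
#' parameters `D_W` and `N`.
#'
#' @param sdlog spread of the log-normal components.
#' @return a [pope_prior()] over the 9 parameters.
#' @export
gm_prior <- function(sdlog = 1.5) {
  mock <- unlist(gm_mock_params())
  margins <- c(
    lapply(mock[1:7], function(m) prior_lognormal(log(m), sdlog)),
    list(prior_beta(2, 2), prior_beta(2, 2)))
  names(margins) <- c("kappa_W", "kappa_WI", "mu_W", "mu_WI", "a", "b",
                      "S_W", "D_W", "N")
  pope_prior(margins)
}

#' @export
plot.gm_profile <- function(x, ...) {
  graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  graphics::plot(x$x, x$W, type = "l", xlab = "x", ylab = "concentration",
                 col = "firebrick", ...)
  graphics::lines(x$x, x$W_I, col = "steelblue")
  graphics::legend("topright", c("Wnt", "Wnt inhibitor"), lty = 1,
                   col = c("firebrick", "steelblue"), bty = "n")
  graphics::plot(x$x, x$P_g, type = "l", xlab = "x",
                 ylab = "cell fraction", col = "darkgreen", ylim = c(0, 1))
  graphics::lines(x$x, x$P_o, col = "orange")
  graphics::legend("topright", c("glycolytic", "oxidative"), lty = 1,
                   col = c("darkgreen", "orange"), bty = "n")
  invisible(x)
}
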