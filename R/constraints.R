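#' Constraint specification
#'
#' A `constraint_spec` couples one summary statistic of a simulator to an
#' inequality (or interval) constraint and to the kernel that scores
#' violations of it.  It is the unit out of which the one-sided ABC
#' likelihood is built: the composite likelihood is the product of the
#' kernel values of all constraints, so every constraint must be (softly)
#' satisfied for the likelihood to be appreciable.
#'
#' Directions follow the optimization reading of the statistics: `"LE"`
#' means the statistic should be at or below the threshold (an objective
#' value to beat, or an upper constraint), `"GE"` at or above it, and
#' `"INTERVAL"` inside `[threshold[1], threshold[2]]`.  The boundary always
#' counts as satisfied.
#'
#' Kernel families:
#' \describe{
#'   \item{`heavyside`}{hard indicator: 1 if satisfied, 0 otherwise.}
#'   \item{`tube`}{hard indicator with slack `epsilon`: 1 if the violation
#'     is at most `epsilon`, 0 otherwise.}
#'   \item{`gaussian_one_sided`}{1 on the satisfied side, quadratic
#'     log-penalty `exp(-(v/epsilon)^2 / 2)` for violation `v > 0`.}
#'   \item{`exponential_one_sided`}{1 on the satisfied side, linear
#'     log-penalty `exp(-v/epsilon)`.}
#' }
#'
#' @param statistic integer index (1-based) of the statistic in the
#'   simulator output vector this constraint applies to.
#' @param direction one of `"LE"`, `"GE"`, `"INTERVAL"`.
#' @param threshold the constraint threshold; a length-2 increasing vector
#'   when `direction == "INTERVAL"`.
#' @param kernel kernel family, see Details.
#' @param epsilon kernel width (softness); must be positive for the soft
#'   families and for `tube`.
#' @param epsilon_min lower floor for `epsilon` used by the online
#'   adaptation; the adapted width never drops below it.
#' @param objective logical; marks this constraint's threshold as an
#'   unknown objective value that threshold adaptation may update.
#'
#' @return an object of class `constraint_spec`.
#' @seealso [composite_log_likelihood()], [run_pope()], [adapt_config()]
#' @export
#' @examples
#' constraint_spec(1, "LE", 27.05, kernel = "gaussian_one_sided", epsilon = 0.01)
#' constraint_spec(2, "INTERVAL", c(2, 4), epsilon = 0.05)
constraint_spec <- function(statistic, direction = c("LE", "GE", "INTERVAL"),
                            threshold, kernel = c("gaussian_one_sided",
                                                  "exponential_one_sided",
                                                  "heavyside", "tube"),
                            epsilon = 0.01, epsilon_min = 0,
                            objective = FALSE) {
  direction <- match.arg(direction)
  kernel <- match.arg(kernel)
  statistic <- as.integer(statistic)
  if (statistic < 1L) stop("`statistic` must be a positive index")
  if (direction == "INTERVAL") {
    if (length(threshold) != 2L || !(threshold[1] < threshold[2]))
      stop("INTERVAL constraints need threshold = c(a, b) with a < b")
  } else if (length(threshold) != 1L) {
    stop("one-sided constraints take a single threshold")
  }
  soft <- kernel %in% c("gaussian_one_sided", "exponential_one_sided", "tube")
  if (epsilon_min < 0) stop("`epsilon_min` must be >= 0")
  if (epsilon < epsilon_min) stop("`epsilon` must be >= `epsilon_min`")
  if (soft && epsilon <= 0) stop("`epsilon` must be > 0 for kernel '", kernel, "'")
  structure(
    list(statistic = statistic, direction = direction,
         threshold = as.numeric(threshold), kernel = kernel,
         epsilon = as.numeric(epsilon), epsilon_min = as.numeric(epsilon_min),
         objective = isTRUE(objective)),
    class = "constraint_spec")
}

#' @export
print.constraint_spec <- function(x, ...) {
  thr <- if (x$direction == "INTERVAL")
    sprintf("[%g, %g]", x$threshold[1], x$threshold[2]) else sprintf("%g", x$threshold)
  cat(sprintf("<constraint> y_%d %s %s  kernel=%s eps=%g (floor %g)%s\n",
              x$statistic,
              switch(x$direction, LE = "<=", GE = ">=", INTERVAL = "in"),
              thr, x$kernel, x$epsilon, x$epsilon_min,
              if (x$objective) "  [objective]" else ""))
  invisible(x)
}

# Signed violation magnitude: 0 when the constraint is satisfied (boundary
# included), otherwise the distance to the nearest satisfying value.
constraint_violation <- function(y_j, spec) {
  switch(spec$direction,
         LE = max(0, y_j - spec$threshold),
         GE = max(0, spec$threshold - y_j),
         INTERVAL = max(0, y_j - spec$threshold[2], spec$threshold[1] - y_j))
}

#' Log kernel value of one constraint
#'
#' Evaluates the constraint kernel in log space (so extreme violations give
#' large negative numbers instead of underflowing to zero).
#'
#' @param y_j observed value of the constrained statistic.
#' @param spec a [constraint_spec()].
#' @return log kernel value in `[-Inf, 0]`.
#' @export
log_kernel <- function(y_j, spec) {
  v <- constraint_violation(y_j, spec)
  if (v <= 0) return(0)
  switch(spec$kernel,
         heavyside = -Inf,
         tube = if (v <= spec$epsilon) 0 else -Inf,
         gaussian_one_sided = -0.5 * (v / spec$epsilon)^2,
         exponential_one_sided = -v / spec$epsilon)
}

#' One-sided constraint kernels
#'
#' Convenience wrappers evaluating a single kernel on the natural (not log)
#' scale.  `heavyside_kernel` ignores the spec's kernel family and always
#' applies the hard indicator; `one_sided_gaussian` and
#' `one_sided_exponential` apply the quadratic and linear log-penalties;
#' `interval_kernel` requires an `INTERVAL` spec and applies the spec's own
#' soft family outside the feasible band.
#'
#' @param y_j observed statistic value.
#' @param spec a [constraint_spec()].
#' @return kernel value in `[0, 1]`.
#' @export
heavyside_kernel <- function(y_j, spec) {
  as.numeric(constraint_violation(y_j, spec) <= 0)
}

#' @rdname heavyside_kernel
#' @export
one_sided_gaussian <- function(y_j, spec) {
  if (spec$epsilon <= 0) stop("one-sided Gaussian kernel requires epsilon > 0")
  v <- constraint_violation(y_j, spec)
  exp(-0.5 * (v / spec$epsilon)^2)
}

#' @rdname heavyside_kernel
#' @export
one_sided_exponential <- function(y_j, spec) {
  if (spec$epsilon <= 0) stop("one-sided exponential kernel requires epsilon > 0")
  v <- constraint_violation(y_j, spec)
  exp(-v / spec$epsilon)
}

#' @rdname heavyside_kernel
#' @export
interval_kernel <- function(y_j, spec) {
  if (spec$direction != "INTERVAL")
    stop("interval_kernel requires an INTERVAL constraint_spec")
  exp(log_kernel(y_j, spec))
}

# Compact numeric representation of a list of specs for the sampler's inner
# loop.  Columns: statistic index, direction code, lo, hi, epsilon, family
# code.  For LE: hi = threshold, lo = -Inf; GE: lo = threshold, hi = Inf.
spec_table <- function(specs) {
  stopifnot(length(specs) > 0)
  tab <- t(vapply(specs, function(s) {
    dir <- match(s$direction, c("LE", "GE", "INTERVAL"))
    lo <- switch(s$direction, LE = -Inf, GE = s$threshold, INTERVAL = s$threshold[1])
    hi <- switch(s$direction, LE = s$threshold, GE = Inf, INTERVAL = s$threshold[2])
    fam <- match(s$kernel, c("heavyside", "tube", "gaussian_one_sided",
                             "exponential_one_sided"))
    c(idx = s$statistic, dir = dir, lo = lo, hi = hi, eps = s$epsilon, fam = fam)
  }, numeric(6)))
  dimnames(tab) <- list(NULL, c("idx", "dir", "lo", "hi", "eps", "fam"))
  tab
}

# Vectorized log composite likelihood over a spec table (internal hot path).
composite_loglik_tab <- function(y, tab) {
  yj <- y[tab[, "idx"]]
  v <- pmax(0, yj - tab[, "hi"], tab[, "lo"] - yj)
  ll <- numeric(nrow(tab))
  hard <- tab[, "fam"] == 1
  tube <- tab[, "fam"] == 2
  gau <- tab[, "fam"] == 3
  ex <- tab[, "fam"] == 4
  ll[hard] <- ifelse(v[hard] > 0, -Inf, 0)
  ll[tube] <- ifelse(v[tube] > tab[tube, "eps"], -Inf, 0)
  ll[gau] <- -0.5 * (v[gau] / tab[gau, "eps"])^2
  ll[ex] <- -v[ex] / tab[ex, "eps"]
  sum(ll)
}

#' Composite log-likelihood of a statistic vector
#'
#' Sum of the per-constraint log kernel values: the log of the product
#' one-sided ABC likelihood.  Every constraint must be satisfied (or softly
#' tolerated) for the result to be finite; a single violated hard kernel, or
#' a degenerate simulation, gives `-Inf`.
#'
#' @param y numeric vector of simulator statistics.
#' @param specs list of [constraint_spec()] objects.
#' @param degenerate logical; set by simulators whose output has no
#'   measurable pattern (e.g. zero spots).  Forces `-Inf`.
#' @return scalar log-likelihood `<= 0`, possibly `-Inf`.
#' @export
#' @examples
#' specs <- list(constraint_spec(1, "LE", 1, epsilon = 0.1))
#' composite_log_likelihood(0.5, specs)   # satisfied: 0
#' composite_log_likelihood(1.1, specs)   # one-epsilon violation: -0.5
composite_log_likelihood <- function(y, specs, degenerate = FALSE) {
  if (isTRUE(degenerate)) return(-Inf)
  idx <- vapply(specs, function(s) s$statistic, integer(1))
  if (any(idx > length(y)))
    stop("constraint references statistic ", max(idx),
         " but the output has only ", length(y), " statistics")
  sum(vapply(specs, function(s) log_kernel(y[s$statistic], s), numeric(1)))
}
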