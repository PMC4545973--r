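---
title: "Optimization posteriors for simulator-based models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimization posteriors for simulator-based models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pope)
```

## The problem and the target distribution

Simulator-based models are usually *optimized*: a black-box search
produces one parameter setting `theta*` that minimizes an objective
subject to constraints.  A single optimum says nothing about parameter
sensitivity, correlations, or how much of parameter space performs
equally well.  This package targets the *optimization posterior*

    pi(theta | y*)  ∝  pi(theta) · P( y(theta) satisfies all constraints )

where `y(theta)` is one stochastic simulator run and "satisfies" means:
the objective statistic comes out at or below the incumbent best value
`y1*`, and every other statistic lands on the right side of its
constraint threshold.  For a single `LE` constraint this probability is
the conditional CDF `F(y* | theta)`, so the posterior has a direct
reading: *the probability that a fresh simulation at `theta` is at least
as good as the incumbent, while feasible*.  Unlike a Gibbs/Boltzmann
weighting of the raw objective (`exp(-beta y)`), this target has no
arbitrary temperature: it is invariant to monotone rescaling of the
objective.

Because the likelihood is a probability under the simulator, everything
runs as likelihood-free (ABC) inference.  Each constraint `j` contributes
a one-sided kernel factor evaluated on a simulated statistic `y_j`:

* `heavyside` — the indicator of satisfaction (ties count as satisfied);
* `tube` — indicator with slack `epsilon`;
* `gaussian_one_sided` — `exp(-(v/epsilon)^2 / 2)` for violation `v > 0`,
  1 otherwise;
* `exponential_one_sided` — `exp(-v/epsilon)`, a linear log-penalty.

Interval constraints score 1 inside `[a, b]` and apply the one-sided
penalty on whichever side is violated.  The composite likelihood is the
product over constraints; all arithmetic is in log space, since
`exp(-(v/epsilon)^2/2)` underflows double precision already at
`v = 40 epsilon`, and a hard chain must distinguish "very unlikely" from
"impossible".

**Direction convention.** One-sided kernel formulas are conventionally
written for one orientation (unit weight where the discrepancy
`d = y - y*` is non-negative), but applications need both: the tumor
pattern case constrains `y1` from below and `y3`, `y4` from above.
Every `constraint_spec` therefore carries an explicit direction, and the
penalty applies on whichever side that direction marks as violated;
nothing is inferred from the algebraic sign in the formula.  The
boundary `y = y*` is satisfied for every family.

## Samplers

`run_pope()` is random-walk Metropolis–Hastings over `theta` with the
likelihood replaced by an `S`-sample Monte-Carlo estimate (default
`S = 1`; more simulations per step rarely repay their cost).  Two modes:

* **pseudo-marginal** — the current state's estimate is carried between
  iterations.  With an unbiased estimate the chain targets the kernel
  posterior exactly; mixing can suffer when a lucky estimate sticks.
* **marginal** — the current state's likelihood is re-estimated with
  fresh simulations every iteration (twice the simulations per step),
  trading a small extra approximation for better mixing.

**Zero-denominator guard (marginal mode).** With hard kernels and small
`S` the refreshed estimate of a *feasible* state is zero with positive
probability.  Taking that zero at face value makes the acceptance ratio
prior-blind (`x/0` accepts regardless of the prior), and an exact
stationary analysis of the resulting chain on the Gaussian testbed shows
a material distortion (Kolmogorov–Smirnov distance 0.02–0.08 to the
target at practical proposal scales).  The marginal mode therefore
adopts a refreshed estimate only if it is positive (or the carried one
is already zero).  For indicator kernels this reduces the chain to
classic ABC-MCMC — propose, simulate once, require feasibility, apply
the prior ratio — which satisfies detailed balance exactly.  For soft
kernels estimates are never exactly zero and the behavior is the
standard marginal (Monte-Carlo-within-Metropolis) sampler.  The
refreshed draw is always recorded as the state's posterior-predictive
`y`, whether or not its estimate was adopted: the draw that created an
accepted state is conditioned on feasibility and would bias
`P(improve)` upward.

**Proposals.** Component-wise Gaussian random walks in a transformed
coordinate chosen from each parameter's support — identity on the real
line, log for positive parameters, logit on finite intervals — with the
Jacobian correction in the acceptance ratio.  This keeps positivity and
unit-interval bounds (e.g. diffusion coefficients, nutrient levels)
without rejection at the boundary.  Scales are per-parameter settings in
the transformed space; the default, 10% of the prior's nominal standard
deviation, is deliberately conservative, and preliminary runs with
`acceptance_report()` (targeting roughly 20–40% acceptance) are the
intended way to tune them.

**Initialization.** A one-sided chain started where constraints fail
rejects every proposal forever, so `initialize_by_rejection()` draws
from the prior until the likelihood estimate is finite and otherwise
reports which constraints bound most often.

**The trace.** One record per iteration, rejections included (a
duplicate record *is* the MCMC sample; `posterior_predictive_summary()`
treats it that way, with an accepted-only view for diagnostics).
Burn-in records are flagged, never deleted.  Each record also snapshots
the current kernel widths and thresholds, and every simulator
evaluation — including rejected proposals and marginal refreshes — is
kept in `attr(trace, "evaluations")`.

## Online adaptation

Kernel widths and unknown objective thresholds can adapt during
burn-in (`adapt_config()`), freezing afterwards so the recorded chain is
plain MCMC:

* **epsilon** — an exponential moving average (decay `delta = 0.9`) of
  each constraint's violation magnitude is pushed into a rolling window
  (500 snapshots); epsilon is reset to the `beta = 0.2` quantile of the
  window, floored at `epsilon_min`.  The small quantile keeps downward
  pressure on epsilon; the floor encodes both computational mercy and
  the analyst's tolerance for that constraint.  Every simulator
  evaluation feeds the average, not only accepted moves: rejected
  proposals carry exactly the information about how hard the
  constraints currently are.  The window quantile (rather than a
  quantile over all history) lets epsilon track the chain into harder
  regions.
* **objective threshold** — deterministic simulators update `y*` to the
  best raw value seen (min for `LE`, max for `GE`); stochastic ones
  update an EMA of the objective (decay `gamma = 0.9`) and move `y*`
  only when the EMA beats it, so an improvement must be *consistently*
  better than the incumbent before it tightens the target.  The EMA
  starts at the incumbent threshold when one exists, which makes
  `gamma = 1` a true no-op.  Threshold adaptation is monotone: `y*` is a
  best-found estimate and never worsens.
* The decay rates can optionally ramp linearly to 1 (`ramp`), an
  alternative to the hard freeze; the default is the hard freeze at the
  end of burn-in.

Window length, decays and quantile are configuration, not constants;
the defaults above were fixed once as round, conventional EMA settings.

## Response models

As an alternative to kernel weighting, `fit_conditional_gaussian()`
fits mean and unbiased covariance to `S` draws at one `theta`
(synthetic likelihood) and `gaussian_cdf_likelihood()` evaluates the
constraint probability analytically as a product of normal orthant or
interval probabilities.  The factorized (independent-marginals) form is
required for more than one statistic; a full covariance CDF is provided
only for `J = 1`.  A zero fitted variance degrades the CDF to a hard
indicator at the mean — the limit of the normal CDF — and is flagged.
In the sampler this estimator *replaces* the epsilon-kernels
(`estimator = "synthetic_gaussian"`, needs `S >= 2`); it is not
composed with them.

## Analytic testbeds

The package validates its samplers against closed forms rather than
against the (qualitative) case studies:

* Gaussian location testbed: `y = theta + sigma z`, prior `N(0, 1)`,
  objective `y <= 0`.  The posterior is `phi(theta) Phi(-theta·2)` up to
  normalization; `analytic_pope_posterior()` computes it by trapezoidal
  quadrature on a grid, including its mean and CDF for
  Kolmogorov–Smirnov comparisons.
* Quadratic testbed: deterministic `y = sum(theta^2)` under a uniform
  prior; with a hard unit threshold the posterior is exactly the prior
  restricted to the unit ball.

These testbeds emulate the two regimes of interest — stochastic
response with analytic CDF, and deterministic response with a hard
feasible set.  What they do not emulate: multimodal responses, heavy
tails, constraint interactions, or degenerate simulations; passing them
validates the inference machinery, not any particular scientific model.

## Case simulator 1: stem-cell niche geometry

A tube of `D = 8` rows models a niche; row sizes are parameterized by
non-negative increments (`theta_1 = 1 + g_1`,
`theta_d = theta_{d-1} + g_d`) so monotone non-decreasing rows are
structural.  Integer capacities round half-up with a floor of one cell.
Soft one-sided Gaussian kernels keep geometries realistic: first
increment below 399 (width 0.1), later increments below 10 or 399
(width 0.1), total size below 400 or 1500 (width 1) — a kernel *prior*
over `g`, with `g >= 0` enforced hard.

The published description of the dynamics is qualitative, so the
cycling model here is the simplest memoryless one: every cell divides
after an independent exponential waiting time (rate 1 per cell, fixing
the time unit at one mean cell cycle), the daughter enters the mother's
row, a full neighborhood chain-displaces toward the open end, and a
cell pushed past row `D` differentiates.  The niche starts full — its
steady operating state — so each division exports one differentiated
cell and the statistic `y` (time to `N = 300` differentiated cells) is
driven by total capacity.  Consequences to keep in mind: absolute times
are simulator-internal (the published `y* = 27.05` lives in unpublished
units and is not comparable), and validation is property-based —
capacity conservation, paired-seed stochastic ordering (bigger niches
are faster), exact recurrence checks, and `1/M` variance shrinkage of
the `M`-replicate statistic.  The shipped experiment configurations
(`pope_fixture_config("A1")` … `"E2"`) reproduce the *structure* of the
published experiment grid — constrained vs. free increments, objective
present/absent/adaptive, the larger total-size budget, replicate
averaging, and the widened objective kernel — with adaptive objectives
where the original used a pre-estimated threshold.

## Case simulator 2: tumor spotting patterns

A one-dimensional activator–inhibitor model of Wnt signalling in colon
cancer tissue, where spots of glycolytic cells form by a Turing
mechanism.  The governing equations of the original simulator are not
public; the reconstruction here uses the classic Gierer–Meinhardt form
with the published parameter roles:

    dW/dt   = kappa_W  W^2 / (a + b W_I) - mu_W  W  + S_W + D_W  W_xx
    dWI/dt  = kappa_WI W^2               - mu_WI W_I       + D_WI WI_xx

with no-flux boundaries on the unit domain.  The inhibitor diffusion
`D_WI` is not among the published parameters and defaults to `50 D_W`,
well inside the Turing regime; it is a grid setting.  The glycolytic
fraction is a smooth decreasing function of Wnt (Wnt suppresses
glycolytic activity): `P_g = N · plogis(-(W - median(W)) / s)` with
`s` 10% of the Wnt dynamic range, and `P_o = 1 - P_g`.  The reaction
terms are swappable via the `reactions` hook of `simulate_gm_1d()`;
everything downstream (spot statistics, constraints, sampling) is
agnostic to them.

Numerics: 256 grid points, semi-implicit stepping (implicit diffusion
via a prefactored Cholesky solve, explicit reactions) at `dt = 5e-4` to
`t = 8`, by which point the pattern is stationary — and a stationary
profile solves the *spatial* discretization alone, so it is independent
of the time integrator.  That is the basis of two checks: an explicit
Euler reference on a 40×-finer time grid agrees to ~2.5e-4 relative L2,
and halving `dt` leaves the spot statistics unchanged within 1%.  Two
further numerical facts are worth stating plainly.  First, the scheme
preserves spatial uniformity exactly, but the homogeneous state is
Turing-*unstable*: machine roundoff is amplified like `exp(lambda t)`
(`lambda ≈ 6` at the Mock parameters), so homogeneity checks use
horizons where that amplification stays far below the tolerance
(`t = 2` gives ~1e5 amplification of 1e-16 noise).  Second, initial
noise is the *pattern seed*: runs are reproducible only at fixed grid
seed.

Spot statistics mirror the published four: maximal runs of grid points
with `P_g` above the mid-level between its extremes (minimum run length
2 to suppress single-point noise) give the count `y2` and mean width
`y1`; `y3` is mean `P_g` outside spots, `y4` the mean Wnt level.  A
flat profile (dynamic range below 1e-4) or zero spots is *degenerate*
and receives zero likelihood — patterns that never formed carry no
information about spot geometry.  The Mock constraint set
(`mock_constraint_specs()`) encodes "different from untreated tissue":
`y1 > 0.604`, `y2` in 2–4, `y3 < 0.807`, `y4 < 5.67`, one-sided
Gaussian kernels with widths (0.01, 0.05, 0.01, 0.05), and a ×10
variant.  The published per-spot mixture weights and Table statistics
depend on the unpublished equations and are not reproduction targets;
the feasibility logic of the constraint table is (and is tested
exactly).

## Problem sizes and test design

The validation suite runs entirely from code-generated data.  Oracle
comparisons pool five pseudo-marginal (and five marginal) chains of
1e5 iterations on the Gaussian testbed, discard 1e4 burn-in each, and
require Kolmogorov–Smirnov distance below 0.02 and posterior-mean error
below 0.02 against quadrature; the quadratic testbed runs 5e4
iterations and must keep every retained sample feasible.  Niche
ordering uses 50 paired seeds; pattern checks run the default 256-point
grid.  `scripts/acceptance.R` recomputes all headline quantities from
scratch at a user-supplied seed.

## Limitations

* Both case simulators are reconstructions of qualitatively described
  systems: inferences about *their* biology are demonstrations, not
  reproductions of published numbers.
* The marginal mode's zero-denominator guard makes hard-kernel chains
  exact but leaves the usual Monte-Carlo-within-Metropolis
  approximation in place for soft kernels.
* Adaptive runs are correct MCMC only after the freeze; recorded
  burn-in exists for diagnostics, not inference.
* No surrogate (Gaussian-process) modeling: every likelihood evaluation
  costs simulations, so very expensive simulators need external
  surrogate machinery.
* The synthetic-likelihood CDF assumes near-Gaussian simulator
  response; multimodal or heavily skewed responses need the kernel
  estimators.
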