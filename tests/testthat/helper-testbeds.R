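# Shared fixtures: analytic oracles and tiny run configurations, all built
# in code at test time.

# Quadrature oracle for the Gaussian location testbed:
# prior N(0,1), y = theta + sigma * z, objective y <= y_star.
gaussian_oracle <- function(sigma = 0.5, y_star = 0,
                            grid = seq(-6, 4, length.out = 4001)) {
  analytic_pope_posterior(function(t) stats::dnorm(t), sigma, y_star, grid)
}

# Oracle for the deterministic quadratic testbed: uniform prior on
# [-2, 2], y = theta^2 <= 1  =>  posterior uniform on [-1, 1].
quadratic_oracle <- function(grid = seq(-2, 2, length.out = 2001)) {
  analytic_pope_posterior(function(t) stats::dunif(t, -2, 2), 0, 1, grid,
                          mean_fn = function(t) t^2)
}

le_heavyside <- function(y_star = 0) {
  list(constraint_spec(1, "LE", y_star, kernel = "heavyside"))
}

# A constraint that is always satisfied (likelihood identically one).
null_constraint <- function() {
  list(constraint_spec(1, "LE", Inf, kernel = "heavyside"))
}

# Minimal trace-shaped data frame for analysis tests.
fake_trace <- function(y, burnin = FALSE, theta = seq_along(y)) {
  df <- data.frame(iteration = seq_along(y) - 1, theta = theta, y_1 = y,
                   log_lik = 0, accepted = TRUE, burnin = burnin)
  class(df) <- c("pope_trace", "data.frame")
  df
}

tiny_gaussian_config <- function(seed = 1, tmpdir = tempdir(),
                                 n_iterations = 200) {
  run_config(
    simulator = list(id = "gaussian_testbed", sigma = 0.5),
    prior = list(list(name = "theta", type = "normal", mean = 0, sd = 1)),
    constraints = list(list(statistic = 1, direction = "LE", threshold = 0,
                            kernel = "heavyside", epsilon = 0.01,
                            epsilon_min = 0, objective = FALSE)),
    sampler = list(mode = "pseudo_marginal", S = 1,
                   n_iterations = n_iterations, burnin = 0,
                   proposal_scales = 1, seed = seed),
    output = list(trace = file.path(tmpdir, sprintf("tiny_%d.tsv", seed))))
}
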