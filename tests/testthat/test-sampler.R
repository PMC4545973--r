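test_that("proposal respects supports and is reproducible", {
  th <- c(0.5, 2, 0.3)
  sup <- rbind(c(-Inf, Inf), c(0, Inf), c(0, 1))
  expect_equal(propose(th, c(0, 0, 0), sup), th)  # zero scales: identity
  set.seed(1)
  for (i in 1:50) {
    p <- propose(th, c(2, 2, 2), sup)
    expect_true(p[2] > 0)
    expect_true(p[3] > 0 && p[3] < 1)
  }
  set.seed(9); a <- propose(th, c(1, 1, 1), sup)
  set.seed(9); b <- propose(th, c(1, 1, 1), sup)
  expect_identical(a, b)
})

test_that("transformed-space walk carries the correct Jacobian correction", {
  sup <- rbind(c(0, Inf), c(0, 1))
  th <- c(2, 0.25); pr <- c(3, 0.5)
  # log walk: |du/dtheta| = 1/theta; logit: (b-a)/((th-a)(b-th))
  expect_equal(log_proposal_ratio(th, pr, sup),
               (-log(2) + log(1 / (0.25 * 0.75))) -
                 (-log(3) + log(1 / (0.5 * 0.5))))
  expect_equal(log_proposal_ratio(th, pr, NULL), 0)
})

test_that("MH acceptance handles -Inf likelihoods without NaN", {
  expect_false(mh_accept(-0.5, -Inf))            # infeasible proposal
  expect_true(mh_accept(-Inf, -0.5))             # escape from zero state
  expect_false(mh_accept(-Inf, -Inf))
  expect_true(mh_accept(-1, -1))                 # identity: alpha = 1
  set.seed(3)
  acc <- mean(vapply(1:4000, function(i) mh_accept(0, log(0.5)), logical(1)))
  expect_equal(acc, 0.5, tolerance = 0.05)       # likelihood ratio 0.5
  # no combination produces NA
  for (a in c(-Inf, -1, 0)) for (b in c(-Inf, -1, 0))
    expect_false(is.na(mh_accept(a, b, -Inf, 0)))
})

test_that("likelihood estimator matches its definition at S = 1 and for synthetic", {
  sim <- function(theta) theta^2          # deterministic
  specs <- list(constraint_spec(1, "LE", 1, epsilon = 0.2))
  cfg <- pope_config(S = 1, n_iterations = 10, seed = 1)
  est <- estimate_log_likelihood(1.1, sim, specs, cfg)
  expect_equal(est$log_lik, composite_log_likelihood(1.1^2, specs))

  degen_sim <- function(theta) list(y = 1, degenerate = TRUE)
  expect_equal(estimate_log_likelihood(0, degen_sim, specs, cfg)$log_lik,
               -Inf)

  set.seed(4)
  noisy <- function(theta) theta + rnorm(1)
  cfg_syn <- pope_config(S = 50, n_iterations = 10, seed = 1,
                         estimator = "synthetic_gaussian")
  set.seed(11)
  est_syn <- estimate_log_likelihood(0.2, noisy, specs, cfg_syn)
  model <- fit_conditional_gaussian(est_syn$y_draws)
  expect_equal(est_syn$log_lik,
               log(gaussian_cdf_likelihood(model, specs)))
})

test_that("rejection initialization finds feasible states or reports failure", {
  prior <- pope_prior(theta = prior_normal(0, 1))
  cfg <- pope_config(S = 1, n_iterations = 10, seed = 2)
  set.seed(2)
  init <- initialize_by_rejection(prior, function(th) th, le_heavyside(0.5),
                                  cfg, max_tries = 200)
  expect_true(is.finite(init$log_lik))
  expect_lte(init$theta, 0.5)

  degen_sim <- function(th) list(y = 0, degenerate = TRUE)
  set.seed(2)
  expect_error(initialize_by_rejection(prior, degen_sim, le_heavyside(0.5),
                                       cfg, max_tries = 20), "degenerate")
  # infeasible hard constraint: prior support never reaches y >= 50
  set.seed(2)
  expect_error(initialize_by_rejection(
    prior, function(th) th,
    list(constraint_spec(1, "GE", 50, kernel = "heavyside")),
    cfg, max_tries = 30), "constraint")
})

test_that("run_pope bookkeeping: record counts, duplicates, simulation accounting", {
  prior <- pope_prior(theta = prior_normal(0, 1))
  sim <- gaussian_test_simulator(0.5)

  tr0 <- run_pope(sim, prior, le_heavyside(0), pope_config(
    n_iterations = 0, seed = 5))
  expect_equal(nrow(tr0), 1)                  # only the initial record

  cfg <- pope_config(n_iterations = 300, burnin = 50, proposal_scales = 1,
                     seed = 5)
  tr <- run_pope(sim, prior, le_heavyside(0), cfg)
  expect_equal(nrow(tr), 301)
  expect_equal(attr(tr, "n_simulations"), 300)   # pseudo-marginal: S per step
  expect_equal(sum(tr$burnin), 51)
  # rejected proposals duplicate the previous record in theta
  rej <- which(!tr$accepted[-1]) + 1
  expect_true(all(tr$theta[rej] == tr$theta[rej - 1]))

  cfgm <- pope_config("marginal", n_iterations = 300, burnin = 50,
                      proposal_scales = 1, seed = 5)
  trm <- run_pope(sim, prior, le_heavyside(0), cfgm)
  expect_equal(attr(trm, "n_simulations"), 600)  # marginal: 2S per step
})

test_that("hard quadratic constraint restricts every retained sample", {
  prior <- pope_prior(theta = prior_uniform(-2, 2))
  cfg <- pope_config(n_iterations = 3000, burnin = 200,
                     proposal_scales = 1.2, seed = 8)
  tr <- run_pope(quadratic_test_simulator(), prior,
                 le_heavyside(1), cfg)
  th <- tr$theta[!tr$burnin]
  expect_true(all(th^2 <= 1))
})

test_that("with constant likelihood the sampler reproduces the prior", {
  prior <- pope_prior(theta = prior_normal(0, 1))
  cfg <- pope_config(n_iterations = 20000, burnin = 1000,
                     proposal_scales = 1, seed = 13)
  tr <- run_pope(function(th) th, prior, null_constraint(), cfg)
  th <- tr$theta[!tr$burnin]
  grid <- seq(-5, 5, length.out = 2001)
  expect_lt(ks_distance(th, grid, pnorm(grid)), 0.02)
})

test_that("fixed seed gives identical traces", {
  prior <- pope_prior(theta = prior_normal(0, 1))
  cfg <- pope_config(n_iterations = 200, proposal_scales = 1, seed = 21)
  tr1 <- run_pope(gaussian_test_simulator(0.5), prior, le_heavyside(0), cfg)
  tr2 <- run_pope(gaussian_test_simulator(0.5), prior, le_heavyside(0), cfg)
  expect_identical(as.data.frame(tr1), as.data.frame(tr2))
})
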