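adapt_specs <- function(eps = 0.5, eps_min = 0.1, thr = 10,
                        objective = FALSE) {
  list(constraint_spec(1, "LE", thr, epsilon = eps, epsilon_min = eps_min,
                       objective = objective))
}

test_that("epsilon adaptation: quantile of the EMA window with a floor", {
  st <- adapt_state_init(adapt_specs(), adapt_config(window = 50))
  # all discrepancies below the floor: epsilon pinned at epsilon_min
  for (i in 1:60) st <- update_epsilons(st, 0.01)
  expect_equal(st$eps, 0.1)
  # constant discrepancy above the floor fills the window: quantile = d0
  st2 <- adapt_state_init(adapt_specs(), adapt_config(window = 50))
  for (i in 1:60) st2 <- update_epsilons(st2, 0.7)
  expect_equal(st2$eps, 0.7)
  # delta = 1 freezes the EMA at its initial value
  st3 <- adapt_state_init(adapt_specs(), adapt_config(delta = 1, window = 50))
  st3 <- update_epsilons(st3, 0.9)
  for (i in 1:20) st3 <- update_epsilons(st3, 0.2)
  expect_equal(st3$ema_d, 0.9)
  expect_equal(st3$eps, 0.9)
})

test_that("objective adaptation: min rule (deterministic) and EMA (stochastic)", {
  st <- adapt_state_init(adapt_specs(thr = 27.05, objective = TRUE),
                         adapt_config(adapt_objective = TRUE,
                                      deterministic = TRUE))
  st <- update_objectives(st, 26.9)
  expect_equal(st$thresholds[[1]], 26.9)
  st <- update_objectives(st, 27.0)           # never worsens
  expect_equal(st$thresholds[[1]], 26.9)

  # gamma = 1: the EMA never leaves the incumbent, threshold unchanged
  stg <- adapt_state_init(adapt_specs(thr = 5, objective = TRUE),
                          adapt_config(adapt_objective = TRUE, gamma = 1))
  for (i in 1:20) stg <- update_objectives(stg, 3 + rnorm(1, sd = 0.1))
  expect_equal(stg$thresholds[[1]], 5)

  # a stream consistently below y* pulls the threshold to the stream mean
  set.seed(31)
  stm <- adapt_state_init(adapt_specs(thr = 5, objective = TRUE),
                          adapt_config(adapt_objective = TRUE, gamma = 0.9))
  thr_path <- numeric(3000)
  for (i in 1:3000) {
    stm <- update_objectives(stm, 3 + rnorm(1, sd = 0.1))
    thr_path[i] <- stm$thresholds[[1]]
  }
  expect_true(all(diff(thr_path) <= 0))        # monotone, never worsens
  expect_lt(abs(stm$thresholds[[1]] - 3), 0.15)
})

test_that("GE objectives adapt with the max rule", {
  st <- adapt_state_init(
    list(constraint_spec(1, "GE", 1, epsilon = 0.1, objective = TRUE)),
    adapt_config(adapt_objective = TRUE, deterministic = TRUE))
  st <- update_objectives(st, 1.4)
  st <- update_objectives(st, 1.2)
  expect_equal(st$thresholds[[1]], 1.4)
})

test_that("freeze stops all adaptation and is idempotent", {
  st <- adapt_state_init(adapt_specs(thr = 5, objective = TRUE),
                         adapt_config(adapt_objective = TRUE,
                                      deterministic = TRUE))
  st <- update_epsilons(st, 0.9)
  st <- freeze(st)
  eps0 <- st$eps; thr0 <- st$thresholds
  st <- update_epsilons(st, 5)
  st <- update_objectives(st, 0.1)
  expect_equal(st$eps, eps0)
  expect_equal(st$thresholds, thr0)
  expect_identical(freeze(st)$active, FALSE)
})

test_that("in-run adaptation: floor respected, objective equals the best evaluation, snapshots freeze", {
  prior <- pope_prior(theta = prior_uniform(-2, 2))
  specs <- list(constraint_spec(1, "LE", Inf, epsilon = 0.2,
                                epsilon_min = 0.05, objective = TRUE))
  cfg <- pope_config("marginal", n_iterations = 800, burnin = 600,
                     proposal_scales = 1, seed = 17)
  ad <- adapt_config(adapt_objective = TRUE, deterministic = TRUE,
                     window = 100)
  tr <- run_pope(quadratic_test_simulator(), prior, specs, cfg,
                 adaptation = ad)
  expect_true(all(tr$eps_1 >= 0.05))
  ev <- attr(tr, "evaluations")
  active <- ev$iteration <= 600
  expect_equal(attr(tr, "final_thresholds")[[1]],
               min(ev$y_1[active & !ev$degenerate]))
  # snapshots constant after the freeze
  post <- tr$iteration > 600
  expect_equal(length(unique(tr$eps_1[post])), 1)
  expect_equal(length(unique(tr$thr_1[post])), 1)
})

test_that("stochastic objective estimate converges to the simulator mean at fixed theta", {
  # at a fixed parameter the best objective estimate is the expected
  # simulator response; the EMA local average recovers it
  set.seed(23)
  st <- adapt_state_init(adapt_specs(thr = Inf, objective = TRUE),
                         adapt_config(adapt_objective = TRUE, gamma = 0.9))
  mu <- 27.05; sdev <- 0.5
  for (i in 1:5000) st <- update_objectives(st, mu + sdev * rnorm(1))
  # EMA sd = sdev * sqrt((1-gamma)/(1+gamma)); the running min sits a few
  # of those below the mean
  ema_sd <- sdev * sqrt(0.1 / 1.9)
  expect_lt(abs(st$thresholds[[1]] - mu), 5 * ema_sd)
})
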