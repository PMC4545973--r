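# smaller grid than the default keeps the unit tests quick; the default
# grid is exercised end to end in the acceptance suite
small_grid <- function(...) gm_grid(n_x = 128, t_final = 4, ...)

test_that("homogeneous steady state solves the reaction fixed point", {
  p0 <- gm_params(0, 127.4, 20.64, 42.36, 1e-8, 1, 1, 0.01, 1)
  expect_equal(gm_steady_state(p0)$W0, 1 / 20.64)     # S_W / mu_W
  p00 <- gm_params(0, 127.4, 20.64, 42.36, 1e-8, 1, 0, 0.01, 1)
  expect_equal(gm_steady_state(p00)$W0, 0)

  p <- gm_mock_params()
  ss <- gm_steady_state(p)
  res_f <- p$kappa_W * ss$W0^2 / (p$a + p$b * ss$WI0) - p$mu_W * ss$W0 + p$S_W
  res_g <- p$kappa_WI * ss$W0^2 - p$mu_WI * ss$WI0
  expect_lt(abs(res_f), 1e-10)
  expect_lt(abs(res_g), 1e-10)
})

test_that("parameter bounds are enforced", {
  expect_error(gm_params(40, 127, 20, 42, 1e-8, 1, 1, 0, 1))      # D_W > 0
  expect_error(gm_params(40, 127, 20, 42, 1e-8, 1, 1, 0.01, 1.5)) # N <= 1
  expect_error(gm_params(40, 127, 20, 42, -1, 1, 1, 0.01, 1))     # a >= 0
})

test_that("zero-noise integration preserves spatial homogeneity", {
  # short horizon: the homogeneous state is Turing-unstable, so roundoff
  # is amplified ~ e^(lambda t); t = 2 keeps that amplification ~1e5,
  # far below the 1e-8 budget from machine precision
  p <- gm_mock_params()
  ss <- gm_steady_state(p)
  prof <- simulate_gm_1d(p, gm_grid(n_x = 128, t_final = 2, noise = 0))
  expect_lt(max(abs(prof$W - ss$W0)), 1e-8)
  expect_lt(max(abs(prof$W_I - ss$WI0)), 1e-8)
})

test_that("linear limit: without autocatalysis Wnt relaxes to S_W / mu_W", {
  p <- gm_params(0, 127.4, 20.64, 42.36, 1e-8, 1, 1, 0.01, 1)
  prof <- simulate_gm_1d(p, gm_grid(n_x = 128, t_final = 2, noise = 0.05))
  expect_true(all(abs(prof$W - 1 / 20.64) / (1 / 20.64) < 0.01))
})

test_that("Mock parameters produce a stable multi-spot Turing pattern", {
  prof <- simulate_gm_1d(gm_mock_params(), small_grid())
  st <- compute_spot_statistics(prof)
  expect_false(st$degenerate)
  expect_gte(st$y[2], 2)
  expect_true(attr(prof, "y2_stable"))
  # field sanity: positivity and consistent cell fractions
  expect_true(all(prof$W >= 0) && all(prof$W_I >= 0))
  expect_equal(prof$P_g + prof$P_o, rep(1, nrow(prof)))
  expect_true(all(prof$P_g >= 0 & prof$P_g <= 1))
  expect_true(all(prof$P_o >= 0 & prof$P_o <= 1))
})

test_that("halving dt leaves the converged spot statistics unchanged within 1%", {
  # full default horizon: the pattern must be stationary for statistics
  # to be integrator-independent
  y_a <- compute_spot_statistics(
    simulate_gm_1d(gm_mock_params(), gm_grid(n_x = 128, dt = 5e-4)))$y
  y_b <- compute_spot_statistics(
    simulate_gm_1d(gm_mock_params(), gm_grid(n_x = 128, dt = 2.5e-4)))$y
  expect_equal(y_a[2], y_b[2])
  for (j in c(1, 3, 4))
    expect_lt(abs(y_a[j] - y_b[j]) / abs(y_b[j]), 0.01)
})

test_that("spot statistics on constructed profiles are exact", {
  # five plateaus of width 0.6 over background 0.8, Wnt constant at 5.67
  dx <- 0.01
  pg <- c(rep(0.8, 40), rep(c(rep(1, 60), rep(0.8, 40)), 5))
  prof <- data.frame(x = (seq_along(pg) - 1) * dx, W = 5.67, P_g = pg)
  st <- compute_spot_statistics(prof)
  expect_false(st$degenerate)
  expect_equal(st$y, c(0.6, 5, 0.8, 5.67))

  # single plateau
  pg1 <- c(rep(0.2, 30), rep(0.9, 25), rep(0.2, 45))
  prof1 <- data.frame(x = (seq_along(pg1) - 1) * dx, W = 2, P_g = pg1)
  st1 <- compute_spot_statistics(prof1)
  expect_equal(st1$y, c(0.25, 1, 0.2, 2))

  # flat profile: degenerate, zero spots, zero composite likelihood
  flat <- data.frame(x = (0:99) * dx, W = 1, P_g = 0.5)
  stf <- compute_spot_statistics(flat)
  expect_true(stf$degenerate)
  expect_equal(stf$y[2], 0)
  expect_equal(composite_log_likelihood(replace(stf$y, 1, 0),
                                        mock_constraint_specs(),
                                        degenerate = stf$degenerate), -Inf)
})

test_that("Mock constraints behave per the feasible-region table", {
  specs <- mock_constraint_specs()
  # a feasible setting: wider spots, fewer of them, lighter background
  expect_equal(composite_log_likelihood(c(0.65, 4, 0.77, 3.25), specs), 0)
  # Mock's own statistics violate the spot-count constraint (5 > 4)
  y_mock <- c(0.604, 5, 0.807, 5.67)
  expect_lt(composite_log_likelihood(y_mock, specs), 0)
  expect_equal(heavyside_kernel(5, specs[[2]]), 0)
  viol <- vapply(specs, function(s)
    heavyside_kernel(y_mock[s$statistic], s) == 0, logical(1))
  expect_equal(which(viol), 2L)
  # the x10 variant widens every kernel tenfold
  expect_equal(vapply(mock_constraint_specs(10), function(s) s$epsilon,
                      numeric(1)), c(0.1, 0.5, 0.1, 0.5))
})

test_that("simulator closure honours the degeneracy contract", {
  # strong decay, no autocatalysis: flat field, no spots
  flat_theta <- c(1e-6, 127.4, 20.64, 42.36, 1e-8, 1, 1, 0.01, 1)
  sim <- pattern_simulator(gm_grid(n_x = 64, t_final = 1))
  out <- sim(flat_theta)
  expect_true(out$degenerate)
  expect_equal(out$y[2], 0)
})
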