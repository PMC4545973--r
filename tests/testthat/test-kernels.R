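test_that("heavyside kernel is the hard constraint indicator, ties satisfied", {
  le <- constraint_spec(1, "LE", 2, kernel = "heavyside")
  expect_equal(heavyside_kernel(1, le), 1)
  expect_equal(heavyside_kernel(3, le), 0)
  expect_equal(heavyside_kernel(2, le), 1)  # boundary counts as satisfied
  ge <- constraint_spec(1, "GE", 2, kernel = "heavyside")
  expect_equal(heavyside_kernel(3, ge), 1)
  expect_equal(heavyside_kernel(1, ge), 0)
  iv <- constraint_spec(1, "INTERVAL", c(2, 4), kernel = "heavyside")
  expect_equal(heavyside_kernel(3, iv), 1)
  expect_equal(heavyside_kernel(4, iv), 1)
  expect_equal(heavyside_kernel(5, iv), 0)
})

test_that("one-sided Gaussian and exponential kernels match their closed forms", {
  gs <- constraint_spec(1, "LE", 5, epsilon = 0.2)
  expect_equal(one_sided_gaussian(5, gs), 1)
  expect_equal(one_sided_gaussian(5 + 0.2, gs), exp(-1 / 2))
  # extreme violation must survive in log space, not underflow
  expect_equal(log_kernel(5 + 10 * 0.2, gs), -50)
  expect_equal(one_sided_gaussian(5 + 10 * 0.2, gs), exp(-50))

  ex <- constraint_spec(1, "LE", 5, kernel = "exponential_one_sided",
                        epsilon = 0.2)
  expect_equal(one_sided_exponential(5 - 1, ex), 1)
  expect_equal(one_sided_exponential(5 + 0.2, ex), exp(-1))
  expect_equal(one_sided_exponential(5 + 0.6, ex), exp(-3))
})

test_that("interval kernel is 1 inside and one-sided outside", {
  giv <- constraint_spec(1, "INTERVAL", c(-1, 2), epsilon = 0.5)
  expect_equal(interval_kernel(0.3, giv), 1)
  expect_equal(interval_kernel(-1, giv), 1)
  expect_equal(interval_kernel(2 + 0.5, giv), exp(-1 / 2))
  eiv <- constraint_spec(1, "INTERVAL", c(-1, 2),
                         kernel = "exponential_one_sided", epsilon = 0.5)
  expect_equal(interval_kernel(-1 - 0.5, eiv), exp(-1))
})

test_that("invalid specifications are rejected", {
  expect_error(constraint_spec(1, "LE", 1, epsilon = 0), "epsilon")
  expect_error(constraint_spec(1, "INTERVAL", c(2, 2)), "a < b")
  expect_error(constraint_spec(1, "LE", 1, epsilon = 0.01,
                               epsilon_min = 0.1), "epsilon")
  expect_error(constraint_spec(0, "LE", 1), "positive index")
})

test_that("composite log-likelihood sums per-constraint logs", {
  specs <- list(constraint_spec(1, "LE", 1, epsilon = 0.1),
                constraint_spec(2, "GE", 0, epsilon = 0.1),
                constraint_spec(3, "LE", 10, kernel = "heavyside"))
  expect_equal(composite_log_likelihood(c(0.5, 1, 2), specs), 0)
  expect_equal(composite_log_likelihood(c(1.1, 1, 2), specs), -0.5)
  expect_equal(composite_log_likelihood(c(0.5, 1, 11), specs), -Inf)
  expect_equal(composite_log_likelihood(c(0.5, 1, 2), specs,
                                        degenerate = TRUE), -Inf)
  expect_error(composite_log_likelihood(c(0.5, 1), specs), "statistic")
})

test_that("kernels are bounded, monotone in violation, and epsilon-limits hold", {
  set.seed(42)
  for (fam in c("gaussian_one_sided", "exponential_one_sided")) {
    s <- constraint_spec(1, "LE", 0, kernel = fam, epsilon = 0.3)
    v <- sort(runif(50, 0, 5))
    k <- exp(vapply(v, log_kernel, numeric(1), spec = s))
    expect_true(all(k > 0 & k <= 1))
    expect_true(all(diff(k) <= 1e-15))          # non-increasing in violation
    expect_equal(exp(log_kernel(-runif(1), s)), 1)  # identically 1 satisfied
    # epsilon -> 0 recovers the indicator; epsilon -> Inf tends to 1
    s0 <- constraint_spec(1, "LE", 0, kernel = fam, epsilon = 1e-9)
    expect_lt(exp(log_kernel(0.5, s0)), 1e-6)
    sI <- constraint_spec(1, "LE", 0, kernel = fam, epsilon = 1e9)
    expect_gt(exp(log_kernel(0.5, sI)), 1 - 1e-6)
  }
})

test_that("composite likelihood factorizes over constraints on random inputs", {
  set.seed(7)
  for (rep in 1:20) {
    specs <- lapply(1:4, function(j)
      constraint_spec(j, sample(c("LE", "GE"), 1), rnorm(1),
                      kernel = sample(c("gaussian_one_sided",
                                        "exponential_one_sided"), 1),
                      epsilon = runif(1, 0.05, 1)))
    y <- rnorm(4)
    expect_equal(composite_log_likelihood(y, specs),
                 sum(vapply(specs, function(s)
                   log_kernel(y[s$statistic], s), numeric(1))))
  }
})
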