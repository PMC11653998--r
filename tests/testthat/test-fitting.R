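# Gompertz estimation: initialization heuristic, least squares, diagnostics.

test_that("initialization heuristic lands near the generating curve", {
  s <- noise_free_series(p_generic, seq(0, 96, by = 2))
  init <- initialize_gompertz(s)
  expect_lt(abs(init$h_max / 1000 - 1), 0.05)
  expect_gt(init$r_max, 0)

  # the screening 12-h grid still yields an admissible starting point
  s12 <- noise_free_series(p_glucose, seq(0, 96, by = 12))
  init12 <- initialize_gompertz(s12)
  expect_true(init12$lag >= 0 && init12$lag <= 96)
  expect_gt(init12$r_max, 0)

  expect_error(
    initialize_gompertz(gas_series("c", 1, seq(0, 48, 12), rep(0, 5))),
    "no production signal")
})

test_that("gas_series enforces its invariants and monotonicity policy", {
  expect_error(gas_series("c", 1, c(0, 12, 24, 36), c(0, 1, 2, 3)),
               "at least 5")
  expect_error(gas_series("c", 1, c(0, 12, 12, 24, 36), 1:5),
               "strictly increasing")
  expect_error(gas_series("c", 1, seq(0, 48, 12), c(0, 5, 4, 8, 9)),
               "decreases at point 3")
  cleaned <- gas_series("c", 1, seq(0, 48, 12), c(0, 5, 4, 8, 9),
                        monotonicity = "clip_to_running_max")
  expect_equal(cleaned$volumes, c(0, 5, 5, 8, 9))
})

test_that("noise-free fits recover generating parameters on the 12-h grid", {
  s <- noise_free_series(p_mixture, seq(0, 96, by = 12))
  fit <- fit_gompertz(s)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$h_max / 991.00 - 1), 1e-3)
  expect_lt(abs(fit$params$r_max / 236.31 - 1), 1e-3)
  expect_lt(abs(fit$params$lag / 33.92 - 1), 1e-3)
  expect_gt(fit$r_squared, 0.9999)
  expect_equal(fit$t95, time_to_fraction(fit$params, 0.95))
})

test_that("noisy pooled triplicates recover parameters within tolerance", {
  sp <- synthetic_batch_spec(p_mixture, grid = seq(0, 96, by = 12),
                             noise_cv = 0.02, seed = 42)
  fit <- fit_gompertz(generate_gas_series(sp))
  expect_true(fit$converged)
  expect_equal(fit$replicate_policy_used, "pool_points")
  expect_equal(fit$n_points, 3 * 9)
  expect_lt(abs(fit$params$h_max / 991.00 - 1), 0.05)
  expect_lt(abs(fit$params$r_max / 236.31 - 1), 0.10)
  expect_lt(abs(fit$params$lag / 33.92 - 1), 0.05)
})

test_that("replicate policies agree on noise-free triplicates", {
  sp <- synthetic_batch_spec(p_generic, grid = seq(0, 96, by = 4),
                             noise_cv = 0, seed = 1)
  reps <- generate_gas_series(sp)
  for (policy in c("pool_points", "fit_means",
                   "fit_per_replicate_then_average")) {
    fit <- fit_gompertz(reps, fit_options(replicate_policy = policy))
    expect_lt(abs(fit$params$h_max / 1000 - 1), 1e-4)
    expect_lt(abs(fit$params$r_max / 250 - 1), 1e-4)
    expect_equal(fit$replicate_policy_used, policy)
  }
  # mismatched condition labels across replicates are refused
  bad <- reps
  bad[[2]]$condition <- "other"
  expect_error(fit_gompertz(bad), "share one condition")
})

test_that("already-saturated plateau curves degrade gracefully", {
  fit <- fit_gompertz(gas_series("flat", 1, seq(0, 48, 12), rep(500, 5)))
  expect_true(!fit$converged || fit$params$lag == 0)
  expect_true(is.na(fit$r_squared))
})

test_that("fits are scale- and time-shift-equivariant", {
  sp <- synthetic_batch_spec(p_mixture, grid = seq(0, 96, by = 12),
                             noise_cv = 0.02, seed = 42, n_replicates = 1)
  s1 <- generate_gas_series(sp)[[1]]
  f1 <- fit_gompertz(s1)
  # volumes scaled by c: Hmax, Rmax scale; lag and R^2 unchanged
  f2 <- fit_gompertz(gas_series("c", 1, s1$times, s1$volumes * 3.7))
  expect_equal(f2$params$h_max, 3.7 * f1$params$h_max, tolerance = 1e-6)
  expect_equal(f2$params$r_max, 3.7 * f1$params$r_max, tolerance = 1e-6)
  expect_equal(f2$params$lag, f1$params$lag, tolerance = 1e-6)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-9)
  # times shifted by +6 h: lag shifts by +6, amplitudes unchanged
  f3 <- fit_gompertz(gas_series("c", 1, s1$times + 6, s1$volumes))
  expect_equal(f3$params$lag, f1$params$lag + 6, tolerance = 1e-6)
  expect_equal(f3$params$h_max, f1$params$h_max, tolerance = 1e-6)
  expect_equal(f3$params$r_max, f1$params$r_max, tolerance = 1e-6)
})

test_that("fitted cost beats a brute-force lattice oracle on small series", {
  # 9-point noise-free series; oracle = exhaustive 50^3 grid search spanning
  # +/-50% around the generating values
  p <- p_generic
  grid <- seq(0, 96, by = 12)
  s <- noise_free_series(p, grid)
  fit <- fit_gompertz(s)
  fit_cost <- sum(fit$residuals^2)

  lat <- expand.grid(h = seq(0.5, 1.5, length.out = 50) * p$h_max,
                     r = seq(0.5, 1.5, length.out = 50) * p$r_max,
                     l = seq(0.5, 1.5, length.out = 50) * p$lag)
  sse <- numeric(nrow(lat))
  for (j in seq_along(grid)) {
    u <- (lat$r * exp(1) / lat$h) * (lat$l - grid[j]) + 1
    sse <- sse + (lat$h * exp(-exp(u)) - s$volumes[j])^2
  }
  expect_lte(fit_cost, min(sse))
})

test_that("goodness_of_fit matches hand-computed R^2", {
  obs <- c(1, 2, 3)
  expect_equal(goodness_of_fit(obs, obs), 1)
  expect_equal(goodness_of_fit(obs, rep(mean(obs), 3)), 0)
  expect_equal(goodness_of_fit(obs, c(1, 2, 4)), 0.5)
  expect_error(goodness_of_fit(c(2, 2, 2), c(1, 2, 3)), "degenerate")
  expect_error(goodness_of_fit(1:3, 1:4), "equal length")
})
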