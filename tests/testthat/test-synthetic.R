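# Synthetic-data generator: noise model, seeding, panels, growth curves.

test_that("zero-noise generation reproduces the model exactly on the grid", {
  grid <- seq(0, 96, by = 12)
  sp <- synthetic_batch_spec(p_glucose, grid = grid, noise_cv = 0,
                             condition = "control")
  for (s in generate_gas_series(sp))
    expect_equal(s$volumes, gompertz_cumulative(p_glucose, grid))
})

test_that("generation is seed-deterministic and replicate-stable", {
  sp <- synthetic_batch_spec(p_mixture, noise_cv = 0.02, seed = 99)
  a <- generate_gas_series(sp)
  b <- generate_gas_series(sp)
  expect_identical(a, b)
  # different seed changes the draw
  sp2 <- synthetic_batch_spec(p_mixture, noise_cv = 0.02, seed = 100)
  expect_false(identical(generate_gas_series(sp2)[[1]]$volumes,
                         a[[1]]$volumes))
  # adding a replicate leaves earlier replicates' data unchanged
  sp5 <- synthetic_batch_spec(p_mixture, noise_cv = 0.02, seed = 99,
                              n_replicates = 5)
  wide <- generate_gas_series(sp5)
  for (r in 1:3) expect_identical(wide[[r]]$volumes, a[[r]]$volumes)
})

test_that("generated curves always satisfy the gas-series invariants", {
  for (cv in c(0.01, 0.02, 0.05)) {
    for (seed in 1:5) {
      sp <- synthetic_batch_spec(p_mixture, noise_cv = cv, seed = seed)
      for (s in generate_gas_series(sp)) {
        expect_s3_class(s, "gas_series")
        expect_true(all(diff(s$volumes) >= 0))
        expect_true(all(s$volumes >= 0))
      }
    }
  }
})

test_that("increment noise is unbiased: Monte-Carlo mean of the final point", {
  # 100 seeds, single replicate each; mean final volume tracks the model
  finals <- vapply(1:100, function(seed) {
    sp <- synthetic_batch_spec(p_mixture, noise_cv = 0.02, seed = seed,
                               n_replicates = 1)
    s <- generate_gas_series(sp)[[1]]
    s$volumes[length(s$volumes)]
  }, numeric(1))
  expect_lt(abs(mean(finals) / gompertz_cumulative(p_mixture, 96) - 1), 0.02)
})

test_that("fitted-parameter dispersion grows with the noise level", {
  meds <- vapply(c(0.01, 0.02, 0.05), function(cv) {
    errs <- vapply(1:25, function(seed) {
      sp <- synthetic_batch_spec(p_mixture, grid = seq(0, 96, by = 2),
                                 noise_cv = cv, seed = seed,
                                 n_replicates = 1)
      fit <- fit_gompertz(generate_gas_series(sp))
      abs(fit$params$h_max / p_mixture$h_max - 1)
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})

test_that("growth generator obeys Monod limits and substrate accounting", {
  m <- monod_params(0.34, 37.70)
  # saturated substrate: early log-OD slope equals mu_max within 1%
  sat <- generate_growth_series(m, 5000, 0.01, 1000, grid = 0:8)
  expect_equal(estimate_specific_growth_rate(sat$growth), 0.34,
               tolerance = 0.01)
  # no substrate: no growth
  none <- generate_growth_series(m, 0, 0.05, 0.5, grid = 0:10)
  expect_true(all(abs(none$growth$od600 - 0.05) < 1e-12))
  # trajectories: OD non-decreasing, substrate non-increasing and >= 0
  g <- generate_growth_series(m, 60, 0.05, 0.5, grid = 0:24)
  expect_true(all(diff(g$growth$od600) >= 0))
  expect_true(all(diff(g$substrate$s_g_per_l) <= 0))
  expect_true(all(g$substrate$s_g_per_l >= 0))
  # cross-module: estimator on noise-free output matches the Monod rate at
  # the early-phase substrate level
  expect_equal(estimate_specific_growth_rate(g$growth), monod_mu(m, 60),
               tolerance = 0.05)
  # noise reproducibility
  n1 <- generate_growth_series(m, 60, 0.05, 0.5, grid = 0:24,
                               noise_cv = 0.02, seed = 5)
  n2 <- generate_growth_series(m, 60, 0.05, 0.5, grid = 0:24,
                               noise_cv = 0.02, seed = 5)
  expect_identical(n1$growth$od600, n2$growth$od600)
})

test_that("screening panels concatenate conditions with a consistent schema", {
  specs <- reference_specs(panel = "wmp_mp_mixtures", noise_cv = 0)
  panel <- generate_screening_panel(specs)
  expect_equal(length(unique(panel$condition)), 7)
  expect_equal(nrow(panel), 7 * 3 * 9)
  expect_true(all(c("condition", "replicate", "time_h", "h2_ml_per_l",
                    "si_g_per_l") %in% names(panel)))

  dup <- list(specs[[1]], specs[[1]])
  expect_error(generate_screening_panel(dup), "duplicate condition")
  expect_error(generate_screening_panel(list()), "non-empty")
})

test_that("reference panel round-trips through the fitting pipeline", {
  # noise off: fitting each mixture condition recovers its generating values
  tab <- reference_panel()
  mix <- tab[tab$panel == "wmp_mp_mixtures", ]
  specs <- reference_specs(panel = "wmp_mp_mixtures", noise_cv = 0,
                           grid = seq(0, 96, by = 2))
  for (i in seq_along(specs)) {
    fit <- fit_gompertz(generate_gas_series(specs[[i]]))
    expect_lt(abs(fit$params$h_max / mix$h_max[i] - 1), 1e-3)
    expect_lt(abs(fit$params$r_max / mix$r_max[i] - 1), 1e-3)
    expect_lt(abs(fit$params$lag / mix$lag[i] - 1), 1e-3)
  }
})
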