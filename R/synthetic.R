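# Synthetic data generation: Gompertz-shaped gas curves with replicate noise,
# Monod-governed growth curves, and multi-condition screening panels with
# known ground truth.

#' Specification of one synthetic batch-fermentation condition
#'
#' Describes how to simulate the replicate cumulative-gas curves of one
#' condition: the generating modified Gompertz parameters, the sampling grid
#' (default the 12-h grid over a 96-h batch), the number of replicate bottles
#' (default triplicate), and the replicate noise level expressed as the
#' coefficient of variation of per-interval production increments.
#'
#' @param params Generating [gompertz_params()].
#' @param grid Sampling times, h; strictly increasing, starting at 0.
#'   Default `seq(0, 96, by = 12)`.
#' @param n_replicates Number of replicate bottles (>= 1, default 3).
#' @param noise_cv Relative standard deviation of per-interval increments
#'   (>= 0, default 0.02).
#' @param seed Integer seed driving all randomness for this condition.
#' @param substrate Optional [substrate_record()] template attached to the
#'   condition.
#' @param condition Condition label.
#'
#' @return An object of class `synthetic_batch_spec`.
#' @export
synthetic_batch_spec <- function(params, grid = seq(0, 96, by = 12),
                                 n_replicates = 3L, noise_cv = 0.02,
                                 seed = 1L, substrate = NULL,
                                 condition = "synthetic") {
  stopifnot(
    inherits(params, "gompertz_params"),
    "grid must be strictly increasing and start at 0" =
      is.numeric(grid) && length(grid) >= 5L && grid[1] == 0 &&
      all(diff(grid) > 0),
    "n_replicates must be >= 1" =
      is.numeric(n_replicates) && n_replicates >= 1L,
    "noise_cv must be >= 0" =
      is.numeric(noise_cv) && length(noise_cv) == 1L && noise_cv >= 0,
    "seed must be a single integer" =
      is.numeric(seed) && length(seed) == 1L && is.finite(seed)
  )
  if (!is.null(substrate)) stopifnot(inherits(substrate, "substrate_record"))
  structure(list(params = params, grid = as.numeric(grid),
                 n_replicates = as.integer(n_replicates),
                 noise_cv = noise_cv, seed = as.integer(seed),
                 substrate = substrate,
                 condition = as.character(condition)),
            class = "synthetic_batch_spec")
}

# Deterministic per-replicate seed stream: replicate r of a spec with seed s
# draws from seed (s + 7919 * r) mod 2^31, so adding replicates never changes
# the data of earlier replicates.
replicate_seed <- function(seed, r) {
  as.integer((as.double(seed) + 7919 * r) %% 2147483647)
}

#' Simulate replicate cumulative gas curves
#'
#' For each replicate, the model increments of [gompertz_cumulative()] over
#' each grid interval are perturbed by multiplicative Gaussian noise
#' `max(0, N(1, noise_cv))` and cumulated from the model value at the first
#' grid point. Applying noise to increments rather than to cumulative values
#' makes monotonicity structural: every generated curve is a valid
#' non-decreasing cumulative series. With `noise_cv = 0` the curves equal the
#' model exactly on the grid. Output is fully reproducible from the spec seed.
#'
#' @param spec A [synthetic_batch_spec()].
#' @return A list of `n_replicates` [gas_series()] objects.
#' @export
#' @examples
#' sp <- synthetic_batch_spec(gompertz_params(991, 236.31, 33.92),
#'                            noise_cv = 0, condition = "mix_1_1")
#' generate_gas_series(sp)[[1]]
generate_gas_series <- function(spec) {
  stopifnot(inherits(spec, "synthetic_batch_spec"))
  model <- gompertz_cumulative(spec$params, spec$grid)
  inc <- diff(model)
  lapply(seq_len(spec$n_replicates), function(r) {
    noisy <- if (spec$noise_cv == 0) inc else withr_seed(
      replicate_seed(spec$seed, r),
      inc * pmax(0, stats::rnorm(length(inc), mean = 1, sd = spec$noise_cv)))
    gas_series(spec$condition, r, spec$grid,
               model[1] + c(0, cumsum(noisy)))
  })
}

#' Simulate a Monod-governed growth curve with substrate depletion
#'
#' Integrates the batch growth system `dX/dt = mu(S) X`,
#' `dS/dt = -mu(S) X / Y_xs` with `mu(S)` the Monod rate, by the classical
#' fixed-step 4th-order Runge-Kutta scheme (step <= 0.05 h), then samples the
#' biomass trajectory on the requested grid and applies multiplicative
#' Gaussian noise to the sampled OD values.
#'
#' @param mu_params A [monod_params()] object.
#' @param s_initial Initial substrate concentration, g/L (>= 0).
#' @param x0 Initial optical density (> 0).
#' @param yield_x_s Biomass yield on substrate, OD units per g/L (> 0).
#' @param grid Sampling times, h; default hourly over 24 h.
#' @param noise_cv Relative SD of the multiplicative OD noise (default 0).
#' @param seed Seed for the noise.
#'
#' @return A list with `growth` (a [growth_series()]) and `substrate`
#'   (data.frame `time_h`, `s_g_per_l` on the same grid).
#' @export
generate_growth_series <- function(mu_params, s_initial, x0, yield_x_s,
                                   grid = 0:24, noise_cv = 0, seed = 1L) {
  stopifnot(
    inherits(mu_params, "monod_params"),
    "s_initial must be >= 0" =
      is.numeric(s_initial) && length(s_initial) == 1L && s_initial >= 0,
    "x0 must be > 0" = is.numeric(x0) && length(x0) == 1L && x0 > 0,
    "yield_x_s must be > 0" =
      is.numeric(yield_x_s) && length(yield_x_s) == 1L && yield_x_s > 0,
    "grid must be strictly increasing, first >= 0" =
      is.numeric(grid) && length(grid) >= 4L && grid[1] >= 0 &&
      all(diff(grid) > 0),
    "noise_cv must be >= 0" = is.numeric(noise_cv) && noise_cv >= 0
  )
  rhs <- function(t, y, parms) {
    mu <- monod_mu(mu_params, max(y[["S"]], 0))
    list(c(X = mu * y[["X"]], S = -mu * y[["X"]] / yield_x_s))
  }
  step <- 0.05
  times <- sort(unique(c(seq(0, max(grid), by = step), grid)))
  sol <- deSolve::ode(y = c(X = x0, S = s_initial), times = times,
                      func = rhs, parms = NULL, method = "rk4")
  idx <- match(grid, sol[, "time"])
  od <- sol[idx, "X"]
  s_traj <- pmax(sol[idx, "S"], 0)
  if (noise_cv > 0)
    od <- withr_seed(seed,
      od * pmax(stats::rnorm(length(od), 1, noise_cv), 1e-6))
  list(growth = growth_series(grid, od),
       substrate = data.frame(time_h = grid, s_g_per_l = s_traj))
}

#' Simulate a multi-condition screening panel
#'
#' Concatenates [generate_gas_series()] over a list of condition specs into
#' one long-format dataset suitable for the end-to-end pipeline
#' ([read_gas_table()] / [fit_gompertz()] / [write_report()]).
#'
#' @param specs A list of [synthetic_batch_spec()] objects with distinct
#'   condition labels.
#' @return A data.frame with columns `condition`, `replicate`, `time_h`,
#'   `h2_ml_per_l`, plus `si_g_per_l`, `sf_g_per_l` where a spec carries a
#'   substrate record.
#' @export
generate_screening_panel <- function(specs) {
  stopifnot(
    "specs must be a non-empty list of synthetic_batch_spec" =
      is.list(specs) && length(specs) >= 1L &&
      all(vapply(specs, inherits, logical(1), "synthetic_batch_spec"))
  )
  labels <- vapply(specs, `[[`, character(1), "condition")
  if (anyDuplicated(labels))
    stop("duplicate condition labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  parts <- lapply(specs, function(sp) {
    series <- generate_gas_series(sp)
    df <- do.call(rbind, lapply(series, function(s)
      data.frame(condition = s$condition, replicate = s$replicate,
                 time_h = s$times, h2_ml_per_l = s$volumes)))
    if (!is.null(sp$substrate)) {
      df$si_g_per_l <- sp$substrate$s_initial
      df$sf_g_per_l <- sp$substrate$s_final
    }
    df
  })
  # substrate columns are per-condition; pad with NA so mixed panels bind
  if (any(vapply(parts, function(d) "si_g_per_l" %in% names(d), logical(1)))) {
    parts <- lapply(parts, function(d) {
      for (col in c("si_g_per_l", "sf_g_per_l"))
        if (!col %in% names(d)) d[[col]] <- NA_real_
      d
    })
  }
  do.call(rbind, parts)
}

#' Synthetic specs for the bundled reference panel
#'
#' Builds one [synthetic_batch_spec()] per row of [reference_panel()], using
#' the panel's parameter triples as generating ground truth. Mixture rows
#' carry their initial-sugar substrate record (96-h duration).
#'
#' @param panel Which sub-panel(s) to include; default all.
#' @param grid,noise_cv,n_replicates,seed Passed to each spec; the per-spec
#'   seed is offset by the row index so conditions draw distinct noise.
#' @return A list of [synthetic_batch_spec()] objects.
#' @export
reference_specs <- function(panel = NULL, grid = seq(0, 96, by = 12),
                            noise_cv = 0.02, n_replicates = 3L, seed = 1L) {
  tab <- reference_panel()
  if (!is.null(panel)) tab <- tab[tab$panel %in% panel, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no panel rows selected", call. = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    synthetic_batch_spec(
      params = gompertz_params(row$h_max, row$r_max, row$lag),
      grid = grid, n_replicates = n_replicates, noise_cv = noise_cv,
      seed = seed + 101L * i,
      substrate = if (!is.na(row$s_initial))
        substrate_record(row$s_initial, duration = 96) else NULL,
      condition = paste(row$panel, row$condition, sep = "/"))
  })
}
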