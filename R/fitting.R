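# Nonlinear least-squares estimation of modified Gompertz parameters from
# cumulative gas time series.

#' Replicate-tagged cumulative gas time series
#'
#' Container for one replicate bottle's cumulative biohydrogen measurements
#' under one experimental condition.
#'
#' @param condition Condition label (substrate or isolate identifier).
#' @param replicate Replicate identifier (coerced to character).
#' @param times Sampling times in hours; strictly increasing, first >= 0.
#' @param volumes Cumulative biohydrogen, mL per L working volume; same length
#'   as `times`, non-negative. Cumulative readings must be non-decreasing;
#'   decreasing readings (measurement jitter) are handled according to
#'   `monotonicity`.
#' @param monotonicity Policy for decreasing cumulative readings: `"reject"`
#'   (default; raise an error naming the first offending index) or
#'   `"clip_to_running_max"` (replace each reading by the running maximum).
#'
#' @return An object of class `gas_series`.
#' @export
#' @examples
#' gas_series("glucose", 1, seq(0, 96, 12),
#'            gompertz_cumulative(gompertz_params(991, 236.31, 33.92), seq(0, 96, 12)))
gas_series <- function(condition, replicate, times, volumes,
                       monotonicity = c("reject", "clip_to_running_max")) {
  monotonicity <- match.arg(monotonicity)
  stopifnot(
    "times and volumes must have equal length" = length(times) == length(volumes),
    "at least 5 points are required" = length(times) >= 5L,
    "times must be finite and start at >= 0" =
      is.numeric(times) && all(is.finite(times)) && times[1] >= 0,
    "times must be strictly increasing" = all(diff(times) > 0),
    "volumes must be finite and non-negative" =
      is.numeric(volumes) && all(is.finite(volumes)) && all(volumes >= 0)
  )
  if (any(diff(volumes) < 0)) {
    if (monotonicity == "reject") {
      bad <- which(diff(volumes) < 0)[1] + 1L
      stop(sprintf(
        "cumulative volume decreases at point %d (condition '%s', replicate '%s'); use monotonicity = 'clip_to_running_max' to clean",
        bad, condition, replicate), call. = FALSE)
    }
    volumes <- cummax(volumes)
  }
  structure(list(condition = as.character(condition),
                 replicate = as.character(replicate),
                 times = as.numeric(times),
                 volumes = as.numeric(volumes)),
            class = "gas_series")
}

#' @export
print.gas_series <- function(x, ...) {
  cat(sprintf("Gas series '%s' replicate '%s': %d points, %.1f-%.1f h, max %.2f mL/L\n",
              x$condition, x$replicate, length(x$times),
              min(x$times), max(x$times), max(x$volumes)))
  invisible(x)
}

#' Fitting options for kinetic model estimation
#'
#' @param bounds Optional named list with elements `h_max`, `r_max`, `lag`,
#'   each a `c(lower, upper)` pair. Entries left `NULL` use data-driven
#'   defaults at fit time: `h_max` in `[0.5, 3] * max(volumes)`, `r_max` in
#'   `[1e-6, 100 * Rmax0]`, `lag` in `[0, max(times)]`.
#' @param max_iterations Maximum optimizer iterations.
#' @param tolerance Convergence tolerance on the relative cost change.
#' @param replicate_policy How to handle multiple replicates:
#'   `"pool_points"` (default; fit all replicate points jointly),
#'   `"fit_means"` (average replicate volumes on the common grid, fit the mean
#'   curve), or `"fit_per_replicate_then_average"` (fit each replicate and
#'   average the parameter estimates).
#' @param multistart Number of additional seeded restarts with the initial
#'   guess perturbed by up to +/-20%; 0 (default) for a fully deterministic
#'   single start.
#' @param multistart_seed RNG seed for the restarts (only used when
#'   `multistart > 0`).
#'
#' @return An object of class `fit_options`.
#' @export
fit_options <- function(bounds = NULL, max_iterations = 200L, tolerance = 1e-10,
                        replicate_policy = c("pool_points", "fit_means",
                                             "fit_per_replicate_then_average"),
                        multistart = 0L, multistart_seed = 1L) {
  replicate_policy <- match.arg(replicate_policy)
  if (!is.null(bounds)) {
    stopifnot("bounds must be a named list" = is.list(bounds))
    for (nm in names(bounds)) {
      b <- bounds[[nm]]
      stopifnot(
        "each bound must be c(lower, upper)" = is.numeric(b) && length(b) == 2L,
        "lower bounds must be >= 0" = b[1] >= 0,
        "lower bound must be below upper" = b[1] < b[2]
      )
    }
  }
  structure(list(bounds = bounds,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance,
                 replicate_policy = replicate_policy,
                 multistart = as.integer(multistart),
                 multistart_seed = as.integer(multistart_seed)),
            class = "fit_options")
}

#' Data-driven starting values for the modified Gompertz fit
#'
#' Tangent-intercept heuristic: `Hmax0` is the largest observed volume;
#' `Rmax0` the steepest forward finite-difference slope (floored at 1e-6);
#' `lag0` the time-axis intercept of the tangent drawn at the left endpoint of
#' the steepest interval, clamped to `[0, max(times)]`.
#'
#' @param series A [gas_series()] object.
#' @return A [gompertz_params()] object usable as a starting point.
#' @export
initialize_gompertz <- function(series) {
  stopifnot(inherits(series, "gas_series"))
  if (all(series$volumes == 0))
    stop("no production signal: all volumes are zero", call. = FALSE)
  h0 <- max(series$volumes)
  slopes <- diff(series$volumes) / diff(series$times)
  r0 <- max(max(slopes), 1e-6)
  i <- which.max(slopes)
  t_slope <- series$times[i]
  lag0 <- min(max(t_slope - series$volumes[i] / r0, 0), max(series$times))
  gompertz_params(h_max = h0, r_max = r0, lag = lag0)
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` of predictions against observations, the
#' goodness-of-fit statistic reported with each kinetic fit.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2).
#' @return R-squared; at most 1, and exactly 1 iff `predicted == observed`.
#' @export
#' @examples
#' goodness_of_fit(c(1, 2, 3), c(1, 2, 4))  # 0.5
goodness_of_fit <- function(observed, predicted) {
  stopifnot(
    "observed and predicted must have equal length >= 2" =
      length(observed) == length(predicted) && length(observed) >= 2L,
    "inputs must be finite numerics" =
      is.numeric(observed) && is.numeric(predicted) &&
      all(is.finite(observed)) && all(is.finite(predicted))
  )
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0)
    stop("degenerate observations: zero total sum of squares", call. = FALSE)
  1 - sum((observed - predicted)^2) / ss_tot
}

# R^2 is undefined for constant observations (zero total sum of squares);
# report NA there instead of failing the whole fit.
safe_r_squared <- function(observed, predicted) {
  tryCatch(goodness_of_fit(observed, predicted),
           error = function(e) NA_real_)
}

# Pool points, mean curve, or per-replicate data according to policy.
assemble_fit_data <- function(series_list, policy) {
  if (policy == "fit_means") {
    grids <- lapply(series_list, `[[`, "times")
    if (length(unique(lapply(grids, function(g) round(g, 9)))) != 1L)
      stop("fit_means requires all replicates on a common time grid", call. = FALSE)
    vol <- rowMeans(do.call(cbind, lapply(series_list, `[[`, "volumes")))
    data.frame(t = grids[[1]], h = vol)
  } else {
    data.frame(t = unlist(lapply(series_list, `[[`, "times")),
               h = unlist(lapply(series_list, `[[`, "volumes")))
  }
}

resolve_bounds <- function(opts, h_obs_max, init) {
  b <- list(h_max = c(0.5 * h_obs_max, 3 * h_obs_max),
            r_max = c(1e-6, 100 * init$r_max),
            lag = c(0, init$lag_upper))
  for (nm in names(opts$bounds %||% list())) b[[nm]] <- opts$bounds[[nm]]
  b
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_gompertz_nls <- function(dat, start, lower, upper, opts) {
  ctrl <- minpack.lm::nls.lm.control(maxiter = opts$max_iterations,
                                     ftol = opts$tolerance)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      h ~ h_max * exp(-exp((r_max * exp(1) / h_max) * (lag - t) + 1)),
      data = dat,
      start = start, lower = lower, upper = upper,
      control = ctrl),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- as.list(coef(fit))
  list(coef = cf, sse = sum(residuals(fit)^2),
       converged = fit$convInfo$isConv %||% TRUE)
}

#' Fit the modified Gompertz model to cumulative gas data
#'
#' Estimates (Hmax, Rmax, lag) by bounded nonlinear least squares
#' (Levenberg-Marquardt via \pkg{minpack.lm}), starting from the
#' [initialize_gompertz()] heuristic. Replicates are combined according to the
#' `replicate_policy` in `options`. The fit is deterministic for identical
#' input and options; an optional seeded multistart is available for difficult
#' curves.
#'
#' @param series A [gas_series()] object or a list of them (replicates of a
#'   single condition; all must share the condition label).
#' @param options A [fit_options()] object.
#'
#' @return An object of class `gompertz_fit` with elements `params`
#'   ([gompertz_params()]), `r_squared`, `t95` (always recomputed from the
#'   fitted parameters via [time_to_fraction()]), `residuals`
#'   (observed - fitted on the fitted point set), `converged`, `n_points`,
#'   `replicate_policy_used`, and `condition`.
#' @export
#' @examples
#' p <- gompertz_params(991, 236.31, 33.92)
#' s <- gas_series("mix", 1, seq(0, 96, 12),
#'                 gompertz_cumulative(p, seq(0, 96, 12)))
#' fit_gompertz(s)
fit_gompertz <- function(series, options = fit_options()) {
  if (inherits(series, "gas_series")) series <- list(series)
  stopifnot(
    "series must be gas_series objects" =
      all(vapply(series, inherits, logical(1), "gas_series")),
    "at least one series is required" = length(series) >= 1L
  )
  cond <- unique(vapply(series, `[[`, character(1), "condition"))
  if (length(cond) != 1L)
    stop("all replicates must share one condition label", call. = FALSE)
  stopifnot(inherits(options, "fit_options"))

  if (options$replicate_policy == "fit_per_replicate_then_average" &&
      length(series) > 1L) {
    sub_opts <- options
    sub_opts$replicate_policy <- "pool_points"
    fits <- lapply(series, fit_gompertz, options = sub_opts)
    par_mat <- vapply(fits, function(f)
      c(f$params$h_max, f$params$r_max, f$params$lag), numeric(3))
    params <- gompertz_params(mean(par_mat[1, ]), mean(par_mat[2, ]),
                              mean(par_mat[3, ]))
    dat <- assemble_fit_data(series, "pool_points")
    pred <- gompertz_cumulative(params, dat$t)
    return(structure(list(
      params = params,
      r_squared = safe_r_squared(dat$h, pred),
      t95 = time_to_fraction(params, 0.95),
      residuals = dat$h - pred,
      converged = all(vapply(fits, `[[`, logical(1), "converged")),
      n_points = nrow(dat),
      replicate_policy_used = options$replicate_policy,
      condition = cond), class = "gompertz_fit"))
  }

  dat <- assemble_fit_data(series, options$replicate_policy)
  # initialization heuristic runs on the first replicate's own curve (pooled
  # replicates share sampling times, which would break the slope heuristic)
  init <- initialize_gompertz(series[[1]])

  b <- resolve_bounds(options, max(dat$h),
                      list(r_max = init$r_max, lag_upper = max(dat$t)))
  lower <- c(h_max = b$h_max[1], r_max = b$r_max[1], lag = b$lag[1])
  upper <- c(h_max = b$h_max[2], r_max = b$r_max[2], lag = b$lag[2])
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  start0 <- list(h_max = clamp(init$h_max, lower[1], upper[1]),
                 r_max = clamp(init$r_max, lower[2], upper[2]),
                 lag = clamp(init$lag, lower[3], upper[3]))

  best <- run_gompertz_nls(dat, start0, lower, upper, options)
  if (options$multistart > 0L) {
    starts <- withr_seed(options$multistart_seed, {
      lapply(seq_len(options$multistart), function(i) {
        f <- stats::runif(3, 0.8, 1.2)
        list(h_max = clamp(start0$h_max * f[1], lower[1], upper[1]),
             r_max = clamp(start0$r_max * f[2], lower[2], upper[2]),
             lag = clamp(start0$lag * f[3], lower[3], upper[3]))
      })
    })
    for (s in starts) {
      cand <- run_gompertz_nls(dat, s, lower, upper, options)
      if (!is.null(cand) && (is.null(best) || cand$sse < best$sse)) best <- cand
    }
  }

  if (is.null(best)) {
    params <- gompertz_params(start0$h_max, start0$r_max, start0$lag)
    converged <- FALSE
  } else {
    params <- gompertz_params(best$coef$h_max, best$coef$r_max, best$coef$lag)
    converged <- isTRUE(best$converged)
  }
  pred <- gompertz_cumulative(params, dat$t)
  structure(list(
    params = params,
    r_squared = safe_r_squared(dat$h, pred),
    t95 = time_to_fraction(params, 0.95),
    residuals = dat$h - pred,
    converged = converged,
    n_points = nrow(dat),
    replicate_policy_used = options$replicate_policy,
    condition = cond), class = "gompertz_fit")
}

# evaluate a block with a local RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.gompertz_fit <- function(x, ...) {
  cat(sprintf(
    "Modified Gompertz fit for '%s' (%s, %d points%s)\n",
    x$condition, x$replicate_policy_used, x$n_points,
    if (x$converged) "" else ", NOT converged"))
  cat(sprintf("  Hmax = %.2f mL/L, Rmax = %.2f mL/L/h, lag = %.2f h\n",
              x$params$h_max, x$params$r_max, x$params$lag))
  cat(sprintf("  t95 = %.2f h, R^2 = %.4f\n", x$t95, x$r_squared))
  invisible(x)
}
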