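# Growth kinetics: exponential-phase specific growth rate from OD600 curves
# and Monod (mu_max, Ks) estimation from (substrate, mu) pairs.

#' Optical-density growth series
#'
#' @param times Sampling times in hours, strictly increasing.
#' @param od600 Optical density at 600 nm, strictly positive, same length as
#'   `times`. At least 4 points.
#'
#' @return An object of class `growth_series`.
#' @export
growth_series <- function(times, od600) {
  stopifnot(
    "times and od600 must have equal length >= 4" =
      length(times) == length(od600) && length(times) >= 4L,
    "times must be finite and strictly increasing" =
      is.numeric(times) && all(is.finite(times)) && all(diff(times) > 0),
    "od600 must be finite and positive" =
      is.numeric(od600) && all(is.finite(od600)) && all(od600 > 0)
  )
  structure(list(times = as.numeric(times), od600 = as.numeric(od600)),
            class = "growth_series")
}

#' Exponential-phase specific growth rate from an OD600 curve
#'
#' Log-linear sliding-window estimator: the specific growth rate mu is the
#' largest slope of `ln(OD600)` versus time over all windows of `window`
#' consecutive points (ordinary least squares within each window). During
#' balanced exponential growth `ln(OD)` is linear in time with slope mu, so
#' the maximum window slope picks out the exponential phase. The estimate is
#' invariant to uniform rescaling of the OD values and floored at 0 (declining
#' cultures report no growth).
#'
#' @param growth A [growth_series()] object.
#' @param window Number of consecutive points per window; at least 3, at most
#'   the series length. Default 4.
#'
#' @return Specific growth rate mu, 1/h (non-negative).
#' @export
#' @examples
#' g <- growth_series(0:10, 0.05 * exp(0.34 * 0:10))
#' estimate_specific_growth_rate(g)  # 0.34
estimate_specific_growth_rate <- function(growth, window = 4L) {
  stopifnot(inherits(growth, "growth_series"))
  n <- length(growth$times)
  if (!is.numeric(window) || length(window) != 1L || window < 3L || window > n)
    stop("window must be between 3 and the series length", call. = FALSE)
  window <- as.integer(window)
  y <- log(growth$od600)
  slopes <- vapply(seq_len(n - window + 1L), function(i) {
    idx <- i:(i + window - 1L)
    tt <- growth$times[idx]
    stats::cov(tt, y[idx]) / stats::var(tt)
  }, numeric(1))
  max(max(slopes), 0)
}

#' Fit the Monod model to (substrate, growth-rate) pairs
#'
#' Least-squares estimation of `mu = mu_max * S / (Ks + S)` by bounded
#' Levenberg-Marquardt, initialized at `mu_max0 = max(mu)` and
#' `Ks0 = median(S)`. At least 3 distinct substrate concentrations are
#' required; for identifiability they should span concentrations below and
#' above the expected Ks. When all observations sit deep in the saturation
#' regime Ks is weakly identified; the result is flagged via `bound_hit`.
#'
#' @param s_i Substrate concentrations, g/L (non-negative).
#' @param mu Observed specific growth rates, 1/h, same length as `s_i`.
#' @param options A [fit_options()] object (bounds entries `mu_max`, `k_s`
#'   honoured; replicate policy ignored).
#'
#' @return An object of class `monod_fit`: `params` ([monod_params()]),
#'   `r_squared`, `residuals`, `converged`, `bound_hit` (TRUE when an
#'   estimate landed on a box bound, signalling weak identifiability).
#' @export
#' @examples
#' s <- c(5, 10, 20, 40, 80, 160)
#' fit_monod(s, 0.34 * s / (37.70 + s))
fit_monod <- function(s_i, mu, options = fit_options()) {
  stopifnot(
    "s_i and mu must have equal length" = length(s_i) == length(mu),
    "s_i must be finite and non-negative" =
      is.numeric(s_i) && all(is.finite(s_i)) && all(s_i >= 0),
    "mu must be finite and non-negative" =
      is.numeric(mu) && all(is.finite(mu)) && all(mu >= 0),
    "at least 3 distinct substrate concentrations are required" =
      length(unique(s_i)) >= 3L
  )
  if (length(unique(mu)) == 1L)
    stop("all growth rates identical: Monod parameters unidentifiable",
         call. = FALSE)
  mu_max0 <- max(mu)
  ks0 <- stats::median(s_i[s_i > 0])
  b <- list(mu_max = c(1e-8, 10 * mu_max0), k_s = c(1e-8, 100 * max(s_i)))
  for (nm in names(options$bounds %||% list()))
    if (nm %in% names(b)) b[[nm]] <- options$bounds[[nm]]
  # residual-function interface: returns best-so-far estimates even when the
  # problem is weakly identified (e.g. all observations at saturation)
  fit <- minpack.lm::nls.lm(
    par = c(mu_max = mu_max0, k_s = ks0),
    lower = c(mu_max = b$mu_max[1], k_s = b$k_s[1]),
    upper = c(mu_max = b$mu_max[2], k_s = b$k_s[2]),
    fn = function(par) mu - par[["mu_max"]] * s_i / (par[["k_s"]] + s_i),
    control = minpack.lm::nls.lm.control(
      maxiter = options$max_iterations, ftol = options$tolerance))
  cf <- fit$par
  tol_edge <- 1e-6
  bound_hit <-
    cf["mu_max"] <= b$mu_max[1] * (1 + tol_edge) ||
    cf["mu_max"] >= b$mu_max[2] * (1 - tol_edge) ||
    cf["k_s"] <= b$k_s[1] * (1 + tol_edge) ||
    cf["k_s"] >= b$k_s[2] * (1 - tol_edge)
  params <- monod_params(unname(cf["mu_max"]), unname(cf["k_s"]))
  pred <- monod_mu(params, s_i)
  structure(list(params = params,
                 r_squared = safe_r_squared(mu, pred),
                 residuals = mu - pred,
                 converged = fit$info %in% 1:4,
                 bound_hit = unname(bound_hit)),
            class = "monod_fit")
}

#' @export
print.monod_fit <- function(x, ...) {
  cat(sprintf("Monod fit: mu_max = %.4f /h, Ks = %.2f g/L (R^2 = %.4f%s)\n",
              x$params$mu_max, x$params$k_s, x$r_squared,
              if (x$bound_hit) ", bound hit" else ""))
  invisible(x)
}
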