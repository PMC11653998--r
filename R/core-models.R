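# Closed-form kinetic equations: modified Gompertz cumulative curve, its
# analytical rate, time-to-fraction, and the Monod growth model.

#' Modified Gompertz parameter set
#'
#' Bundles the three parameters of the modified Gompertz model (MGM) of
#' cumulative gas production: the asymptotic maximum cumulative biohydrogen
#' `h_max` (mL per L working volume), the maximum production rate `r_max`
#' (mL/L/h, the slope at the inflection point), and the lag phase `lag`
#' (h, the intercept of the inflection tangent with the time axis).
#'
#' @param h_max Maximum cumulative biohydrogen production, mL/L. Must be
#'   positive and finite.
#' @param r_max Maximum biohydrogen production rate, mL/L/h. Must be positive
#'   and finite.
#' @param lag Lag phase lambda, h. Must be non-negative and finite.
#'
#' @return An object of class `gompertz_params` (a named list).
#' @seealso [gompertz_cumulative()], [gompertz_rate()], [time_to_fraction()]
#' @export
#' @examples
#' gompertz_params(h_max = 991, r_max = 236.31, lag = 33.92)
gompertz_params <- function(h_max, r_max, lag) {
  stopifnot(
    "h_max must be a finite positive scalar" =
      is.numeric(h_max) && length(h_max) == 1L && is.finite(h_max) && h_max > 0,
    "r_max must be a finite positive scalar" =
      is.numeric(r_max) && length(r_max) == 1L && is.finite(r_max) && r_max > 0,
    "lag must be a finite non-negative scalar" =
      is.numeric(lag) && length(lag) == 1L && is.finite(lag) && lag >= 0
  )
  structure(list(h_max = h_max, r_max = r_max, lag = lag),
            class = "gompertz_params")
}

#' @export
print.gompertz_params <- function(x, ...) {
  cat(sprintf(
    "Modified Gompertz parameters: Hmax = %.2f mL/L, Rmax = %.2f mL/L/h, lag = %.2f h\n",
    x$h_max, x$r_max, x$lag))
  invisible(x)
}

#' Monod growth parameter set
#'
#' @param mu_max Maximum specific growth rate, 1/h. Must be positive.
#' @param k_s Substrate affinity (half-saturation) constant, g/L. Must be
#'   positive. At a substrate concentration equal to `k_s` the specific growth
#'   rate is `mu_max / 2`.
#'
#' @return An object of class `monod_params` (a named list).
#' @seealso [monod_mu()], [fit_monod()]
#' @export
#' @examples
#' monod_params(mu_max = 0.34, k_s = 37.70)
monod_params <- function(mu_max, k_s) {
  stopifnot(
    "mu_max must be a finite positive scalar" =
      is.numeric(mu_max) && length(mu_max) == 1L && is.finite(mu_max) && mu_max > 0,
    "k_s must be a finite positive scalar" =
      is.numeric(k_s) && length(k_s) == 1L && is.finite(k_s) && k_s > 0
  )
  structure(list(mu_max = mu_max, k_s = k_s), class = "monod_params")
}

#' @export
print.monod_params <- function(x, ...) {
  cat(sprintf("Monod parameters: mu_max = %.4f /h, Ks = %.2f g/L\n",
              x$mu_max, x$k_s))
  invisible(x)
}

check_time <- function(t) {
  if (!is.numeric(t) || length(t) == 0L || any(!is.finite(t)) || any(t < 0))
    stop("t must be finite and non-negative", call. = FALSE)
  invisible(t)
}

# Inner exponent u(t) = (Rmax*e/Hmax)*(lag - t) + 1 shared by the cumulative
# and rate forms. The "+1" places the inflection tangent so that the lag is
# the tangent's time-axis intercept (Zwietering parameterization); it also
# makes the closed-form time-to-fraction the exact inverse of the curve.
gompertz_u <- function(params, t) {
  (params$r_max * exp(1) / params$h_max) * (params$lag - t) + 1
}

#' Cumulative biohydrogen production under the modified Gompertz model
#'
#' Evaluates `H(t) = Hmax * exp(-exp((Rmax*e/Hmax) * (lag - t) + 1))`, the
#' three-parameter sigmoidal model of cumulative product formation. The curve
#' is strictly increasing, bounded above by `h_max`, and has its maximum slope
#' `r_max` at the inflection point `t = lag + Hmax/(Rmax*e)`.
#'
#' @param params A [gompertz_params()] object.
#' @param t Time in hours; non-negative scalar or vector. Vector input returns
#'   a vector in the same order.
#'
#' @return Cumulative biohydrogen volume(s), mL/L.
#' @export
#' @examples
#' p <- gompertz_params(1617.67, 870.77, 28.37)
#' gompertz_cumulative(p, c(24, 36, 48, 96))
gompertz_cumulative <- function(params, t) {
  stopifnot(inherits(params, "gompertz_params"))
  check_time(t)
  params$h_max * exp(-exp(gompertz_u(params, t)))
}

#' Biohydrogen production rate under the modified Gompertz model
#'
#' The exact time derivative of [gompertz_cumulative()]: with
#' `u(t) = (Rmax*e/Hmax)*(lag - t) + 1`,
#' `R(t) = Rmax * exp(u(t) - exp(u(t)) + 1)`. The rate attains its maximum
#' value `r_max` exactly at the inflection point
#' `t* = lag + Hmax/(Rmax*e)`, where `u(t*) = 0`.
#'
#' @inheritParams gompertz_cumulative
#' @return Production rate(s), mL/L/h.
#' @export
#' @examples
#' p <- gompertz_params(1617.67, 870.77, 28.37)
#' tstar <- p$lag + p$h_max / (p$r_max * exp(1))
#' gompertz_rate(p, tstar)  # equals r_max
gompertz_rate <- function(params, t) {
  stopifnot(inherits(params, "gompertz_params"))
  check_time(t)
  u <- gompertz_u(params, t)
  params$r_max * exp(u - exp(u) + 1)
}

#' Time at which a given fraction of maximum production is reached
#'
#' Closed-form inverse of the modified Gompertz curve:
#' `t_f = (Hmax/(Rmax*e)) * (1 - ln(-ln f)) + lag`. The default
#' `fraction = 0.95` gives the t95 statistic commonly reported alongside the
#' fitted parameters: the time at which 95% of the maximal cumulative
#' biohydrogen has been produced.
#'
#' @param params A [gompertz_params()] object.
#' @param fraction Target fraction of `h_max`, strictly between 0 and 1.
#'   May be a vector.
#'
#' @return Time(s) in hours at which `gompertz_cumulative()` equals
#'   `fraction * h_max`. Can be negative for very small fractions of curves
#'   with short lag (the model is defined on the whole real line even though
#'   observations start at t = 0).
#' @export
#' @examples
#' time_to_fraction(gompertz_params(991, 236.31, 33.92))        # t95
#' time_to_fraction(gompertz_params(991, 236.31, 33.92), 0.5)   # half-production
time_to_fraction <- function(params, fraction = 0.95) {
  stopifnot(inherits(params, "gompertz_params"))
  if (!is.numeric(fraction) || length(fraction) == 0L ||
      any(!is.finite(fraction)) || any(fraction <= 0) || any(fraction >= 1))
    stop("fraction must lie strictly between 0 and 1", call. = FALSE)
  params$h_max / (params$r_max * exp(1)) * (1 - log(-log(fraction))) + params$lag
}

#' Monod specific growth rate
#'
#' Evaluates `mu = mu_max * S / (Ks + S)`: the specific growth rate as a
#' saturating function of substrate concentration, with half-maximal rate at
#' `S = Ks`.
#'
#' @param params A [monod_params()] object.
#' @param s_i Substrate (initial reducing sugar) concentration, g/L;
#'   non-negative scalar or vector.
#'
#' @return Specific growth rate(s), 1/h.
#' @export
#' @examples
#' monod_mu(monod_params(0.34, 37.70), 37.70)  # half-saturation: 0.17
monod_mu <- function(params, s_i) {
  stopifnot(inherits(params, "monod_params"))
  if (!is.numeric(s_i) || length(s_i) == 0L || any(!is.finite(s_i)) || any(s_i < 0))
    stop("s_i must be finite and non-negative", call. = FALSE)
  params$mu_max * s_i / (params$k_s + s_i)
}
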