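# Derived process metrics: experimental summaries, substrate yield,
# volumetric productivity, substrate uptake, mixture improvement, and
# assembly of screening-style kinetic report rows.

#' Substrate record for one fermentation condition
#'
#' @param s_initial Total initial reducing sugar, g/L (> 0).
#' @param s_final Residual reducing sugar at the end of fermentation, g/L;
#'   optional (`NA` when not measured), must satisfy
#'   `0 <= s_final <= s_initial` when present.
#' @param duration Fermentation time, h (> 0).
#'
#' @return An object of class `substrate_record`.
#' @export
substrate_record <- function(s_initial, s_final = NA_real_, duration) {
  stopifnot(
    "s_initial must be a positive scalar" =
      is.numeric(s_initial) && length(s_initial) == 1L &&
      is.finite(s_initial) && s_initial > 0,
    "duration must be a positive scalar" =
      is.numeric(duration) && length(duration) == 1L &&
      is.finite(duration) && duration > 0,
    "s_final must be a scalar (possibly NA)" =
      length(s_final) == 1L && (is.na(s_final) || is.numeric(s_final))
  )
  if (!is.na(s_final) && (s_final < 0 || s_final > s_initial))
    stop("s_final must lie in [0, s_initial]", call. = FALSE)
  structure(list(s_initial = s_initial, s_final = as.numeric(s_final),
                 duration = duration),
            class = "substrate_record")
}

#' Experimental summary of replicate gas curves
#'
#' Mean and standard error, over replicates, of (a) the maximum observed
#' cumulative volume (`h_max_exp`) and (b) the experimental maximum production
#' rate `R_Emax` defined as the largest forward finite-difference slope
#' `dH/dt` of each replicate's cumulative curve. The standard error is the
#' sample standard deviation (n - 1 denominator) divided by `sqrt(n)`, and 0
#' by convention for a single replicate.
#'
#' @param replicates A [gas_series()] object or list of them.
#' @return A list with elements `h_max_exp`, `h_max_se`, `r_emax_exp`,
#'   `r_emax_se`, `n`.
#' @export
experimental_summary <- function(replicates) {
  if (inherits(replicates, "gas_series")) replicates <- list(replicates)
  stopifnot(
    "at least one replicate is required" = length(replicates) >= 1L,
    "replicates must be gas_series objects" =
      all(vapply(replicates, inherits, logical(1), "gas_series"))
  )
  maxima <- vapply(replicates, function(s) max(s$volumes), numeric(1))
  slopes <- vapply(replicates, function(s)
    max(diff(s$volumes) / diff(s$times)), numeric(1))
  n <- length(replicates)
  se <- function(x) if (n == 1L) 0 else stats::sd(x) / sqrt(n)
  list(h_max_exp = mean(maxima), h_max_se = se(maxima),
       r_emax_exp = mean(slopes), r_emax_se = se(slopes),
       n = n)
}

#' Biohydrogen yield per gram of initial reducing sugar
#'
#' `Y_HP/s (mL/g) = H_total / S_i`: total cumulative biohydrogen divided by
#' the total initial reducing sugar concentration.
#'
#' @param h_total Cumulative biohydrogen produced, mL/L (>= 0).
#' @param substrate A [substrate_record()] object (its `s_initial` is used).
#'
#' @return Yield, mL per g of initial reducing sugar.
#' @export
#' @examples
#' yield_per_substrate(991.00, substrate_record(14.34, duration = 96))  # 69.11
yield_per_substrate <- function(h_total, substrate) {
  stopifnot(
    "h_total must be a non-negative scalar" =
      is.numeric(h_total) && length(h_total) == 1L &&
      is.finite(h_total) && h_total >= 0,
    inherits(substrate, "substrate_record")
  )
  h_total / substrate$s_initial
}

#' Volumetric biohydrogen productivity
#'
#' `Q_p (mL/L/h) = H_total / t`: cumulative biohydrogen divided by the
#' fermentation time over which it was produced.
#'
#' @param h_total Cumulative biohydrogen produced, mL/L (>= 0).
#' @param duration Fermentation time, h (> 0).
#'
#' @return Productivity, mL/L/h.
#' @export
#' @examples
#' volumetric_productivity(1617.67, 60)  # 26.96
volumetric_productivity <- function(h_total, duration) {
  stopifnot(
    "h_total must be a non-negative scalar" =
      is.numeric(h_total) && length(h_total) == 1L &&
      is.finite(h_total) && h_total >= 0,
    "duration must be a positive scalar" =
      is.numeric(duration) && length(duration) == 1L &&
      is.finite(duration) && duration > 0
  )
  h_total / duration
}

#' Substrate uptake rate
#'
#' `Q_s (g/L/h) = (S_initial - S_final) / t`: reducing sugar consumed per unit
#' fermentation time. Requires the residual sugar measurement.
#'
#' @param substrate A [substrate_record()] with `s_final` present.
#' @return Uptake rate, g/L/h (0 when no sugar was consumed).
#' @export
substrate_uptake_rate <- function(substrate) {
  stopifnot(inherits(substrate, "substrate_record"))
  if (is.na(substrate$s_final))
    stop("residual sugar required: s_final is missing", call. = FALSE)
  (substrate$s_initial - substrate$s_final) / substrate$duration
}

#' Relative improvement of one condition over a reference
#'
#' `100 * (h_new - h_reference) / h_reference`: the percent change in maximum
#' cumulative biohydrogen relative to a reference substrate, used to quantify
#' synergy of substrate mixtures over the sole substrates.
#'
#' @param h_new Cumulative biohydrogen of the condition of interest, mL/L.
#' @param h_reference Cumulative biohydrogen of the reference condition, mL/L
#'   (> 0).
#'
#' @return Percent improvement (negative when `h_new < h_reference`).
#' @export
#' @examples
#' relative_improvement(991.00, 900.67)  # 10.03
relative_improvement <- function(h_new, h_reference) {
  stopifnot(
    "h_new must be a finite scalar" =
      is.numeric(h_new) && length(h_new) == 1L && is.finite(h_new),
    "h_reference must be a positive scalar" =
      is.numeric(h_reference) && length(h_reference) == 1L &&
      is.finite(h_reference) && h_reference > 0
  )
  100 * (h_new - h_reference) / h_reference
}

#' Assemble one kinetic report row
#'
#' Combines the experimental replicate summary, the fitted modified Gompertz
#' parameters and the derived process metrics into one row of a
#' screening-style kinetic table. `t95` is always recomputed from the fitted
#' parameters via [time_to_fraction()], never taken from the input. Yield and
#' uptake are populated only when a substrate record is supplied; productivity
#' only when a duration is available (the substrate record's duration, or
#' `qp_duration`).
#'
#' @param condition Condition label.
#' @param replicates A [gas_series()] or list of them.
#' @param fit A `gompertz_fit` from [fit_gompertz()]. Non-converged fits are
#'   refused unless `force = TRUE`.
#' @param substrate Optional [substrate_record()].
#' @param qp_duration Optional duration (h) for the productivity denominator,
#'   overriding the substrate record's duration. By default the duration is
#'   the time at which the observed cumulative maximum is first reached.
#' @param final_ph Optional final pH, passed through.
#' @param force Allow a non-converged fit.
#'
#' @return An object of class `kinetic_report_row` (a named list); absent
#'   metrics are `NA`.
#' @export
build_report_row <- function(condition, replicates, fit, substrate = NULL,
                             qp_duration = NULL, final_ph = NA_real_,
                             force = FALSE) {
  stopifnot(inherits(fit, "gompertz_fit"))
  if (!fit$converged && !force)
    stop("fit did not converge; pass force = TRUE to report it anyway",
         call. = FALSE)
  if (!is.null(substrate)) stopifnot(inherits(substrate, "substrate_record"))
  if (inherits(replicates, "gas_series")) replicates <- list(replicates)
  es <- experimental_summary(replicates)

  # default Qp denominator: first time the observed maximum is reached
  if (is.null(qp_duration)) {
    qp_duration <- if (!is.null(substrate)) substrate$duration else {
      t_at_max <- vapply(replicates, function(s)
        s$times[which(s$volumes >= max(s$volumes) - 1e-12)[1]], numeric(1))
      mean(t_at_max)
    }
  }

  h_total <- es$h_max_exp
  structure(list(
    condition = as.character(condition),
    h_max_exp = es$h_max_exp, h_max_se = es$h_max_se,
    r_emax_exp = es$r_emax_exp, r_emax_se = es$r_emax_se,
    n_replicates = es$n,
    lag = fit$params$lag, r_max = fit$params$r_max,
    h_max_fit = fit$params$h_max,
    t95 = time_to_fraction(fit$params, 0.95),
    r_squared = fit$r_squared,
    yield_hp_s = if (!is.null(substrate))
      yield_per_substrate(h_total, substrate) else NA_real_,
    q_p = if (!is.null(qp_duration) && is.finite(qp_duration) && qp_duration > 0)
      volumetric_productivity(h_total, qp_duration) else NA_real_,
    q_s = if (!is.null(substrate) && !is.na(substrate$s_final))
      substrate_uptake_rate(substrate) else NA_real_,
    s_initial = if (!is.null(substrate)) substrate$s_initial else NA_real_,
    final_ph = final_ph),
    class = "kinetic_report_row")
}

#' @export
print.kinetic_report_row <- function(x, ...) {
  cat(sprintf(
    "Kinetic report row '%s': Hmax(exp) %.2f +/- %.2f, Rmax %.2f, lag %.2f, t95 %.2f h\n",
    x$condition, x$h_max_exp, x$h_max_se, x$r_max, x$lag, x$t95))
  invisible(x)
}
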