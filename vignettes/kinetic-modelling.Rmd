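---
title: "Modelling batch dark-fermentation biohydrogen kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling batch dark-fermentation biohydrogen kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(h2kinetics)
```

## The model and its assumptions

Batch dark fermentation produces a sigmoidal cumulative biohydrogen curve:
a lag while the inoculum adapts, a roughly exponential rise driven by
growth-associated hydrogen evolution, and a plateau as substrate is exhausted
and metabolism shifts to by-products. h2kinetics describes this curve with
the three-parameter modified Gompertz model in the Zwietering
parameterization,

$$H(t) = H_{max}\,\exp\!\left\{-\exp\!\left[\frac{R_{max}\,e}{H_{max}}(\lambda - t) + 1\right]\right\},$$

where $H_{max}$ (mL per L working volume) is the production asymptote,
$R_{max}$ (mL/L/h) the slope at the inflection point, and $\lambda$ (h) the
lag phase. These parameters are *defined geometrically*: the tangent at the
inflection point has slope $R_{max}$ and intersects the time axis at
$\lambda$. That geometric definition is exactly what the "+1" inside the
inner exponent encodes — without it, the time-axis intercept of the
inflection tangent is not $\lambda$, and the widely used closed-form
expression for the time to 95% of maximal production,

$$t_{95} = \frac{H_{max}}{R_{max}\,e}\bigl[1 - \ln(-\ln 0.95)\bigr] + \lambda,$$

is no longer the inverse of the curve. The literature that reports
$(H_{max}, R_{max}, \lambda, t_{95})$ tables is self-consistent only under
the "+1" form, which is why the package implements it: for the steep
glucose-screen parameter sets bundled in `reference_panel()` the two variants
differ by $H_{max}/(R_{max}e) \approx 0.7$ h in $t_{95}$, and only the "+1"
form reproduces the tabulated values. `time_to_fraction()` generalizes the
expression to any fraction $f \in (0,1)$.

The production-rate curve is the exact derivative of $H$: with
$u(t) = (R_{max}e/H_{max})(\lambda - t) + 1$,

$$R(t) = R_{max}\,\exp\bigl[u(t) - e^{u(t)} + 1\bigr],$$

which attains $R_{max}$ exactly at the inflection point
$t^* = \lambda + H_{max}/(R_{max}e)$ where $u(t^*) = 0$. Rate expressions in
parts of the applied literature are typeset inconsistently (duplicated
bracket terms that do not differentiate the cumulative form); the package
derives the rate analytically rather than reproducing any printed variant,
and the test suite checks it against central finite differences
($<10^{-6}$ relative) and by trapezoidal re-integration of the curve
($<10^{-4}$ relative).

Growth kinetics follow the Monod model
$\mu = \mu_{max} S / (K_s + S)$ with $\mu_{max}$ (1/h) the maximum specific
growth rate and $K_s$ (g/L) the substrate affinity constant; $K_s$ carries
the same units as the substrate concentration, here g/L of reducing sugar.

Model assumptions worth keeping in mind: gas volumes are taken as already
normalized to reference conditions (1 atm, 25 °C) per litre of working
volume; cumulative readings are monotone up to measurement jitter; one
Gompertz curve describes one condition (no diauxie, no second production
phase); and the Monod relation is evaluated against the *initial* sugar
concentration of each medium, as is conventional in batch screening work.

## Fitting

`fit_gompertz()` estimates $(H_{max}, R_{max}, \lambda)$ by bounded
Levenberg–Marquardt nonlinear least squares (`minpack.lm::nlsLM`). The
starting point is data-driven (`initialize_gompertz()`): $H_{max}^0$ is the
largest observed volume; $R_{max}^0$ the steepest forward finite-difference
slope (floored at $10^{-6}$); $\lambda^0$ the time-axis intercept of the
tangent drawn at the left endpoint of the steepest interval, clamped to
$[0, \max t]$. Default box bounds are
$H_{max} \in [0.5, 3] \cdot \max H_{obs}$,
$R_{max} \in [10^{-6}, 100 R_{max}^0]$, $\lambda \in [0, \max t]$; they
prevent divergence on flat or truncated curves while leaving realistic fits
interior. Convergence uses a relative cost-change tolerance of $10^{-10}$
and at most 200 iterations.

Replicate bottles are combined by one of three policies: `pool_points`
(default) fits all replicate points jointly, using all information and
remaining deterministic; `fit_means` fits the replicate-mean curve, mimicking
tables built from mean curves; `fit_per_replicate_then_average` averages
per-replicate estimates. $R^2 = 1 - SS_{res}/SS_{tot}$ is always computed on
the point set actually fitted, matching the single $R^2$ per condition in
screening tables. The fit is deterministic by default; a seeded multistart
(`fit_options(multistart = n)`, initial guesses perturbed by ±20%) exists
for pathological curves but is off by default — determinism first.

Decreasing cumulative readings are either rejected with an error naming the
offending row (default) or clipped to the running maximum
(`monotonicity = "clip_to_running_max"`), a deliberate choice between
surfacing instrument problems and tolerating benign jitter.

Degenerate inputs behave predictably: an all-zero series raises
"no production signal"; an already-saturated plateau has an unidentifiable
lag and returns $\lambda$ at its lower bound with $R^2 = NA$ (the total sum
of squares is zero, so $R^2$ is undefined rather than silently 0 or 1).

### Identifiability and the sampling grid

Screening experiments commonly sample every 12 h over 96 h. For the steep
curves in `reference_panel()` (rise time $H_{max}/R_{max}$ of 2–8 h) that
grid leaves at most one or two points between lag and plateau: $H_{max}$ and
$\lambda$ remain well determined, but $R_{max}$ is essentially set by a
single interval and is not statistically identifiable. The package therefore
runs its *validation* experiments — the zero-noise round trips over the full
reference panel and the 100-experiment stochastic-recovery ensemble — on a
2-h grid, which resolves the rise phase; this is a property of the
experimental design, not of the estimator, and each test states the grid it
uses. On noise-free 12-h data the fit still recovers exact parameters (the
data lie on the model manifold), and at 2% increment noise the pooled
triplicate fit on the 12-h grid stays within 5%/10%/5% for
$H_{max}/R_{max}/\lambda$, which the suite also checks.

## Growth-rate estimation and Monod fitting

`estimate_specific_growth_rate()` implements the log-linear exponential-phase
estimator: the slope of $\ln(\mathrm{OD}_{600})$ against time in the
steepest sliding window. The window defaults to 4 consecutive points — wide
enough to suppress single-point noise on an hourly grid, narrow enough to
stay inside a typical 6–10 h exponential phase. The estimate is invariant to
uniform OD rescaling (calibration-free) and floored at 0.

`fit_monod()` estimates $(\mu_{max}, K_s)$ from $(S_i, \mu)$ pairs by
bounded least squares on the residual function directly
(`minpack.lm::nls.lm`), initialized at $\mu_{max}^0 = \max \mu$,
$K_s^0 = \mathrm{median}\,S_i$. The residual interface returns best-so-far
estimates even for weakly identified data; when all observations sit deep in
the saturation regime ($S_i \gg K_s$) the $K_s$ estimate typically lands on
a box bound and the result carries `bound_hit = TRUE` as an explicit
weak-identifiability flag. Identifiable designs need concentrations both
below and above the expected $K_s$.

## Process metrics and reporting conventions

The derived metrics are literal quotients: yield
$Y_{HP/s} = H/S_i$ (mL/g), volumetric productivity $Q_p = H/t$ (mL/L/h),
substrate uptake $Q_s = (S_i - S_f)/t$ (g/L/h), and percent improvement
$100(H_{new} - H_{ref})/H_{ref}$. Three conventions matter:

- For glucose control media the yield denominator is the *nominal added*
  glucose (60 g/L for a 6% medium), not nominal plus the base medium's own
  5 g/L glucose; this is the convention under which published control yields
  reproduce exactly.
- The $Q_p$ denominator defaults to the time at which the observed cumulative
  maximum is first reached (production has effectively stopped there);
  a fixed duration can be supplied instead (`qp_duration`).
- Experimental summaries report means and standard errors over replicates
  with the sample (n−1) standard deviation divided by $\sqrt n$, and SE = 0
  by convention for a single replicate. The experimental maximum rate
  $R_{Emax}$ is the largest forward finite-difference slope per replicate —
  a definition that on a 12-h grid is bounded by $\Delta H / 12$ and is
  *not* comparable in magnitude to the fitted $R_{max}$ for steep curves;
  the package reports both without attempting to reconcile them.

`build_report_row()` recomputes $t_{95}$ from the fitted parameters rather
than trusting any stored value, and leaves metrics absent (`NA`, rendered as
blank, never 0) when their inputs are missing. `write_report()` renders 2
decimal places (3 for $R^2$ and $Q_s$) with byte-deterministic output.

## The synthetic-data generator

`generate_gas_series()` emulates replicate screening curves: the model
increments over each grid interval are multiplied by
$\max(0, \mathcal N(1, cv))$ noise and re-cumulated from the model value at
the first grid point. Applying noise to *increments* rather than cumulative
readings makes monotonicity structural — every generated curve is a valid
cumulative series by construction — and leaves increments unbiased;
truncation at zero introduces negligible bias at $cv \le 5\%$ (at
$cv = 0.02$ the truncation probability is $\Phi(-50) \approx 0$). Defaults
mirror a standard screening design: 12-h grid over 96 h, triplicates. The
default $cv = 0.02$ is deliberately harsher than the replicate scatter
implied by published standard errors of a few mL/L on curves of ~1000 mL/L,
so recovery tests are meaningful rather than trivially tight. Each replicate
draws from its own deterministic seed stream
($(seed + 7919r) \bmod 2^{31}-1$), so adding replicates never changes
earlier replicates' data.

`generate_growth_series()` integrates the batch growth system
$dX/dt = \mu(S)X$, $dS/dt = -\mu(S)X/Y_{X/S}$ with the classical fixed-step
RK4 scheme (step 0.05 h, via `deSolve`), samples on the requested grid and
applies multiplicative OD noise. Negative-control conditions are emulated
simply as specs with small $H_{max}$, not as a separate mechanism.

What the generator does *not* emulate: CO2 scrubbing and headspace-pressure
dynamics, the discretization of water-displacement volume readings,
systematic (non-random) drift between replicates, and any coupling between
substrate depletion and the gas curve. Passing recovery tests therefore
demonstrate estimator correctness under the stated noise model, not
robustness to every artefact of real gas measurements.

## Validation harness and problem sizes

The package validates itself at three levels, all seeded and text-only:

- exact-value checks of the closed forms against tabulated parameter/t95/
  yield/improvement combinations from the bundled reference panel;
- zero-noise round trips (generate → fit, every panel triple, 2-h grid,
  tolerance 0.1%) and a brute-force grid-search oracle on 9-point series
  (the fitted cost must not exceed the minimum over a $50^3$ lattice
  spanning ±50% around the generating values);
- a stochastic-recovery ensemble: 100 independent triplicate experiments at
  $cv = 0.02$ on the 2-h grid, requiring median absolute relative errors
  below 2% ($H_{max}$), 5% ($R_{max}$) and 3% ($\lambda$). The ensemble
  size balances quantile stability against test runtime (it completes in
  well under a minute on one core); `parameter_recovery()` and the CLI
  `recover` command expose the same harness for larger runs.

## Numerical choices

- $e$ is the machine-precision constant `exp(1)`, not a truncated 2.71828;
  the difference is below $10^{-5}$ relative on every derived quantity.
- In IEEE double arithmetic the curve reaches exactly 0 far before the lag
  and exactly $H_{max}$ far after saturation (the inner $\exp(-e^u)$
  under/overflows); strict positivity, strict upper boundedness and strict
  monotonicity are guaranteed on the representable window — fractions
  roughly in $[10^{-300}, 1 - 10^{-16}]$ — and the closed bounds hold
  everywhere.
- `time_to_fraction()` may return times before 0 for very small fractions of
  short-lag curves; it reports the model's answer and leaves windowing to
  the caller.
- Ties in the steepest-interval search of the initialization heuristic
  resolve to the earliest interval (`which.max`), a deterministic choice.

## Known limitations

No parameter-uncertainty quantification (profile likelihood, bootstrap); no
weighted least squares; no model selection against logistic or Richards
alternatives; no multiple-comparison statistics for screening tables; no gas
law corrections. These are deliberate non-goals — the package is the kinetic
core of a screening workflow, not a statistics suite.
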