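# h2kinetics

Kinetic analysis of cumulative biohydrogen production from batch dark
fermentation, for bioprocess researchers screening fermentative isolates and
feedstocks (e.g. fruit and vegetable peel wastes) in serum-bottle batch
experiments.

## The model

Cumulative biohydrogen `H(t)` (mL per L working volume) is described by the
three-parameter modified Gompertz model in the Zwietering parameterization,

    H(t) = Hmax · exp{ −exp[ (Rmax·e/Hmax)·(λ − t) + 1 ] }

with asymptote `Hmax` (mL/L), maximum production rate `Rmax` (mL/L/h, the
slope at the inflection point) and lag phase `λ` (h, the time-axis intercept
of the inflection tangent). Its exact derivative gives the production-rate
curve, and its closed-form inverse gives the time to any production fraction,

    t_f = (Hmax/(Rmax·e)) · [1 − ln(−ln f)] + λ ,

reported for `f = 0.95` as **t95**. Growth kinetics follow the Monod model
`µ = µmax·S/(Ks + S)`. Around these the package provides:

- bounded Levenberg–Marquardt fitting of `(Hmax, Rmax, λ)` to replicate gas
  curves with data-driven initialization (`fit_gompertz`), and of
  `(µmax, Ks)` to `(S, µ)` pairs (`fit_monod`);
- the exponential-phase growth-rate estimator for OD600 curves
  (`estimate_specific_growth_rate`);
- process metrics: substrate yield `Y_HP/s = H/Si`, volumetric productivity
  `Qp = H/t`, substrate uptake `Qs = (Si − Sf)/t`, and percent improvement
  between substrates (`relative_improvement`);
- screening-style report tables (`build_report_row`, `write_report`), a
  long-format CSV interchange schema (`read_gas_table`), and a CLI
  (`exec/h2kin`: `simulate | fit | report | recover`);
- a synthetic-data generator with known ground truth (`synthetic_batch_spec`,
  `generate_gas_series`, `generate_growth_series`, `reference_panel`) and a
  seeded parameter-recovery harness (`parameter_recovery`).

## Worked example

Simulate a triplicate 96-h batch experiment (2-h sampling, 2% replicate
noise on production increments) for a watermelon:melon peel 1:1 mixture with
known parameters, then refit and derive the process metrics:

```r
library(h2kinetics)

spec <- synthetic_batch_spec(
  gompertz_params(h_max = 991, r_max = 236.31, lag = 33.92),
  grid = seq(0, 96, by = 2), noise_cv = 0.02, seed = 7,
  condition = "WMP:MP 1:1")
reps <- generate_gas_series(spec)
fit <- fit_gompertz(reps)
fit
#> Modified Gompertz fit for 'WMP:MP 1:1' (pool_points, 147 points)
#>   Hmax = 998.01 mL/L, Rmax = 238.09 mL/L/h, lag = 33.92 h
#>   t95 = 40.04 h, R^2 = 0.9999

row <- build_report_row("WMP:MP 1:1", reps, fit,
                        substrate = substrate_record(14.34, 0, 96))
sprintf("yield %.2f mL/g, Qp %.2f mL/L/h, improvement over WMP %.2f%%",
        row$yield_hp_s, row$q_p, relative_improvement(row$h_max_exp, 900.67))
#> "yield 69.59 mL/g, Qp 10.40 mL/L/h, improvement over WMP 10.81%"
```

The fit recovers the generating parameters to well under 1%: `Hmax` 998 vs
991 mL/L, `Rmax` 238.1 vs 236.3 mL/L/h, `λ` 33.92 h exactly, and `t95`
40.04 h against the closed-form 40.05 h of the generating triple. The yield
(69.59 mL of H2 per g of initial reducing sugar) and productivity follow
directly from the experimental maximum; the improvement compares the mixture
against a sole-watermelon-peel reference of 900.67 mL/L.

The same pipeline runs from the shell:

```sh
exec/h2kin simulate --out panel.csv --noise-cv 0.02 --seed 7
exec/h2kin fit --input panel.csv --out report.csv --json fits.json
```

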