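# adaptvd

Compartmental pharmacokinetic modelling for drugs that precipitate and
bioaccumulate in tissue on prolonged dosing — such as clofazimine, which
forms insoluble crystal-like inclusions inside spleen macrophages over
months of treatment. Classical constant-volume compartmental models cannot
track the resulting soluble-to-insoluble phase transition: they overpredict
early and underpredict late tissue concentrations. `adaptvd` makes the
apparent volume of distribution *adaptive*: the tissue (spleen) compartment
volume is multiplied by a parametric, monotone expansion function f(t) with
f(0) = 1, and the associated rate constants are scaled by 1/f(t).

The core model (two compartments; an optional third peripheral compartment
is supported) is

    dA1/dt = -(K/f(t) + K12) A1 + (K21/f(t)) A2      C1 = A1 / V1
    dA2/dt =   K12 A1         - (K21/f(t)) A2        C2 = A2 / (V2 f(t))

with bolus dosing into serum (A1). Five expansion families are available:
constant (base model), linear `1 + X t`, exponentiated Hill
`exp(Emax t^H / (T50^H + t^H))`, and baseline-normalised logistic and
rational square-root sigmoids.

For whom: pharmacometricians and PK modellers analysing chronic-dosing
tissue-distribution studies (NONMEM-style datasets), and anyone needing a
self-contained simulator/estimator for time-varying-Vd models.

The package provides:

* `expansion_fn()`, `fx_eval()`, `inflection_time()`,
  `time_to_fraction_of_plateau()` — the expansion-function calculus;
* `structural_model()`, `build_schedule()`, `simulate_profile()` — compiled
  adaptive Dormand–Prince simulation with dose events, trough convention
  and exact mass balance, plus `analytic_two_compartment()` as an
  independent closed-form oracle;
* `fit_model()`, `compare_models()`, `bootstrap()` — extended-least-squares
  maximum likelihood with proportional error, AIC/R² model comparison,
  weighted-residual diagnostics and a design-preserving stratified
  bootstrap;
* `vd_total()`, `half_life()`, `cumulative_fraction_sequestered()`,
  `per_dose_fraction_sequestered()`, `derived_trajectory()`, `consensus()`
  — time-varying derived PK and cross-model consensus;
* `generate_study()` — a synthetic generator emulating the destructive
  mouse study design (25 mg/kg Mon–Fri for 20 weeks, cohorts sampled at
  days 7…140 at trough);
* `read_dataset()`/`write_dataset()` (NONMEM-style CSV) and
  `run_pipeline()` (config-driven end-to-end workflow; CLI in
  `inst/cli/adaptvd.R`).

## Worked example

```r
library(adaptvd)

# Published base-model parameters: terminal half-life
base <- structural_model(
  pk_parameters(V1 = 2.43, V2 = 0.00516, K = 0.033, K12 = 0.183,
                K21 = 0.00287))
half_life(base, 0)
#> [1] 21.04906        # the published 21-day terminal half-life

# Dosing arithmetic: cumulative load at the 50%-expansion time
sched <- build_schedule(25, 20)       # 25 mg/kg Mon-Fri, 20 weeks
cumulative_dose(sched, 98.1) / 1000
#> [1] 1.75            # g/kg: 14 complete weeks x 5 doses x 25 mg/kg

# Simulate and fit a synthetic study
truth <- structural_model(
  pk_parameters(V1 = 60, V2 = 0.1, K = 0.3, K12 = 0.3, K21 = 6),
  expansion_fn("hill_exp", Emax = 5, T50 = 60, Hill = 3))
ds <- generate_study(truth, study_design(), error_model(0.2, 0.2), seed = 7)
ds
#> <study_dataset> 40 observations, 20 animals, days {7, 14, 28, 56, 84, 114, 140}, 100 doses
#>   synthetic (seed 7 )

cmp <- compare_models(ds, list(base = structural_model(truth$parameters),
                               hill_exp = truth),
                      fixed = c("V1", "K12", "Hill"), n_multistart = 3,
                      seed = 2)
cmp[, 1:5]
#>      model p      ofv      aic r_squared
#> 1 hill_exp 7 175.7151 189.7151 0.9646938
#> 2     base 5 194.8162 204.8162 0.9620608
```

The adaptive-Vd model beats the constant-volume base model by ~15 AIC
points on data generated with a sigmoid expansion; `p` counts estimated
parameters (the sigmoid family carries the extra expansion parameters).
`derived_trajectory()` then gives the time-varying total Vd, half-life and
sequestered dose fractions for the fitted model, and `consensus()`
averages them across sigmoid families.

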