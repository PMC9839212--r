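# jishuku

Voluntary going-out restraint (*jishuku*) under repeated non-punitive
emergency declarations: a stigma model with habituation, and the panel
estimators to test its prediction on prefecture-by-day mobility data.

## The problem

During the COVID-19 pandemic Japan restrained mobility without legal
penalties: prefecture-level states of emergency asked people to stay
home, and compliance rested on social pressure. The first declaration
cut going-out sharply; later ones visibly less. `jishuku` packages a
formal account of that fading response and the tools to measure it:

* **Theory.** Going out pays
  `u_out − φ [γc + ι σ e^{−h(n)} s(x)]^δ`, staying home pays `u_home`.
  The psychological cost mixes infection risk `γc` with a social stigma
  `σ s(x)` that is active only under a declaration (`ι = 1`), falls with
  the share `x` of people already out (`s' < 0`), and is discounted by
  habituation `e^{−h(n)}` as the declaration count `n` grows.
  Sensitivities `φ` follow a distribution `F`, so the equilibrium
  going-out share solves `x* = χ(x*) = F(φ̂(s(x*)))`. The model yields a
  closed-form no-emergency share `x₀* = F((u_out − u_home)/(γc)^δ)`, a
  strictly positive self-restraint effect `R = x₀* − x₁*` whenever
  stigma is active, and `∂R/∂n < 0`: every repetition erodes the
  effect.
* **Measurement.** A one-way error-component panel regression of
  mobility change on per-number declaration dummies
  (`emergency_1st` … `emergency_4th`) plus weather, lagged infection
  and holiday covariates, estimated within prefecture with
  cluster-robust standard errors; and a spatial-error random-effects
  model with AR(1) serial correlation
  (`ν_t = ρWν_t + η_t`, `η_t = ψη_{t−1} + e_t`) estimated by maximum
  likelihood.
* **Synthetic data.** A generator that reproduces the study's panel
  structure — the printed 2020–2021 Japanese declaration schedule
  (packaged as a fixture), weather-like covariates, holiday calendar,
  and disturbances with unit effects plus spatial and serial
  correlation — so every estimator is testable offline at desk scale.

## Worked example

Habituation in the theory model — the same emergency, declared four
times, loses most of its bite:

```r
library(jishuku)

p <- theory_params(u_out = 1, u_home = 0, gamma = 0.5, c = 2,
                   sigma = 1, delta = 1)
F <- sensitivity_dist("logistic", location = 0.8, scale = 0.2)
s <- stigma_curve("affine", s0 = 2, s1 = 0.5)
h <- habituation_curve("linear", rate = 0.5)
habituation_sweep(p, F, s, h, n_max = 4)
#> # A tibble: 4 × 6
#>       n    x0     x1     R     k n_stable
#>   <int> <dbl>  <dbl> <dbl> <int>    <int>
#> 1     1 0.726 0.0774 0.649     1        1
#> 2     2 0.726 0.155  0.572     1        1
#> 3     3 0.726 0.292  0.434     1        1
#> 4     4 0.726 0.457  0.269     1        1
```

Without an emergency 72.6% of the population goes out (`x0`). The first
declaration pushes the share down to 7.7% (`x1`), a self-restraint
effect `R = 0.649`; by the fourth declaration habituation has eroded
`R` to 0.269. `autoplot()` on the sweep draws the same table.

The empirical pipeline on a synthetic panel at the study's dimensions
(47 prefectures × 518 days, true retail effects
−0.2009/−0.0644/−0.0605/−0.0088):

```r
cfg <- panel_config(seed = 42)
panel <- assemble_panel(cfg)          # 24,346 rows, packaged schedule
fit <- fit_within_fe(panel, "retail",
  c("emergency_1st", "emergency_2nd", "emergency_3rd", "emergency_4th",
    "precipitation_adj", "temperature_z", "windspeed_adj",
    "positive_per1000_l1", "national_holiday", "unofficial_holiday"))
tidy(fit)
#> # A tibble: 10 × 5
#>    term                estimate std.error statistic   p.value
#>    <chr>                  <dbl>     <dbl>     <dbl>     <dbl>
#>  1 emergency_1st       -0.203    0.00113    -180.   0
#>  2 emergency_2nd       -0.0626   0.00132     -47.3  0
#>  3 emergency_3rd       -0.0614   0.00220     -27.9  6.71e-171
#>  4 emergency_4th       -0.0130   0.00578      -2.25 2.48e-  2
#>  5 precipitation_adj   -0.0199   0.000214    -92.9  0
#>  6 temperature_z        0.00998  0.000231     43.2  0
#>  7 windspeed_adj       -0.0105   0.000546    -19.3  1.21e- 82
#>  8 positive_per1000_l1 -0.438    0.0985       -4.44 8.82e-  6
#>  9 national_holiday     0.0408   0.000892     45.8  0
#> 10 unofficial_holiday   0.0276   0.00124      22.2  1.89e-109
```

The within estimator recovers the habituation pattern: negative
declaration effects whose magnitude shrinks with the declaration
number. `run_declaration_models()` repeats this for all four mobility
categories, pooled or by number, with the fixed-effects or the
spatial-error AR(1) estimator (`fit_spatial_ar()`), and
`run_pipeline()` drives theory sweep, panel generation and estimation
from one YAML/list config with fully seeded randomness.

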