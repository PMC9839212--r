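---
title: "Stigma, habituation and self-restraint: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stigma, habituation and self-restraint: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jishuku)
```

## The decision model

`jishuku` studies voluntary going-out restraint under repeated,
non-punitive emergency declarations of the kind Japan used during the
COVID-19 pandemic. A unit population chooses between going out and
staying home. Going out pays

$$u_{\mathrm{out}} - \phi\,\bigl[\gamma c + \iota\,\sigma\,
  e^{-h(n)} s(x)\bigr]^{\delta},$$

staying home pays $u_{\mathrm{home}}$. The bracket collects the two
psychological costs of going out: infection risk $\gamma c$ (probability
times cost) and, while an emergency is declared ($\iota = 1$), a social
stigma $\sigma s(x)$ whose level falls with the share $x$ of people
already outside ($s' < 0$, $s(1) > 0$). Individuals differ only in their
sensitivity $\phi \ge 0$, distributed with cdf $F$ and density $f$.
An individual goes out iff $\phi \le \hat\phi$, with the critical
sensitivity

$$\hat\phi = \frac{u_{\mathrm{out}} - u_{\mathrm{home}}}
  {[\gamma c + \iota \sigma e^{-h(n)} s(x)]^{\delta}},$$

so the share choosing to go out when share $x$ is already out is the
best-response map $\chi(x) = F(\hat\phi(s(x)))$. Equilibria are fixed
points $x^* = \chi(x^*)$. Because $s$ is decreasing and $F$
nondecreasing, $\chi$ is nondecreasing and maps $[0,1]$ into itself, so
a fixed point always exists; there can be several.

The habituation discount $e^{-h(n)}$, with $h$ increasing in the
declaration count $n$ and $h(1) = 0$, is the model's distinctive
ingredient: each repetition of the same non-binding announcement blunts
the stigma of being seen outside. Three consequences, all verified by
the test suite as sampled properties:

* without an emergency the equilibrium has the closed form
  $x_0^* = F\!\bigl((u_{\mathrm{out}} - u_{\mathrm{home}})/(\gamma
  c)^{\delta}\bigr)$ and is unique;
* the self-restraint effect $R = x_0^* - x_1^*$ is strictly positive
  whenever the stigma channel is active ($\sigma > 0$, finite $h$);
* treating $n$ as continuous, the implicit-function derivative
  $\partial x_1^*/\partial n = (\partial\chi/\partial n)\,/\,(1 -
  \partial\chi/\partial x)$ is positive at stable equilibria when
  $h' > 0$, hence $\partial R/\partial n < 0$: the effect erodes with
  every repetition.

## Functional families

The model fixes only shape restrictions for $F$, $s$ and $h$, so the
package supplies minimal families satisfying them, selectable per run:

* `sensitivity_dist()`: uniform on $[0, \max]$; a location–scale
  logistic truncated to the positive half line; lognormal. All three are
  continuous with a density — a requirement, since the comparative
  statics in $n$ involve $f$. Distributions with atoms are out of scope.
* `stigma_curve()`: affine $s(x) = s_0 - (s_0 - s_1)x$ and power
  $s(x) = s_1 + (s_0 - s_1)(1 - x)^\kappa$, both strictly decreasing
  with $s_1 = s(1) > 0$.
* `habituation_curve()`: linear $h(n) = \lambda (n-1)$ and logarithmic
  $h(n) = \lambda \ln n$, both with $h(1) = 0$ so the first declaration
  carries the full stigma; `rate = 0` switches habituation off.

## Equilibrium computation

`find_equilibria()` scans $\chi(x) - x$ on a uniform grid (step
$10^{-3}$) for sign changes and refines each bracket with bisection to a
$10^{-12}$ root tolerance; reported equilibria used for comparative
statics are additionally polished by a damped Newton step to near
machine precision, so that finite differences of the equilibrium in $n$
(step $10^{-5}$) are clean. Stability is flagged by the local slope of
$\chi$ (central finite difference, step $10^{-6}$; one-sided at the
boundaries): slope $< 1$ is stable. Tangential (double) roots would make
the slope test borderline; they are non-generic and surface as a
missing bracket or a slope near 1, not silently.

Under multiplicity the default reporting rule is the **smallest stable**
fixed point — the most restrained outcome, consistent with bounding the
emergency share by $\chi(1)$ in the positivity argument for $R$ — and is
configurable (`largest-stable`, `smallest`, `largest`). Because raising
$n$ shifts $\chi$ up pointwise, the smallest fixed point is monotone in
$n$ under this rule, which keeps the habituation sweep well defined even
when $k > 1$.

Two numerical caveats documented by the property suites: first, with a
uniform $F$ the map can saturate ($x^* = 1$) when the support ends below
the critical sensitivity; admissible test configurations therefore draw
the uniform upper endpoint beyond the no-emergency threshold. Second,
when parameters push the emergency equilibrium below roughly $10^{-6}$,
consecutive values of $R(n)$ can tie in double precision although they
are strictly ordered mathematically; the property suites require a
numerically interior equilibrium ($\chi(0) \ge 10^{-6}$), since strict
monotonicity below machine epsilon is unobservable in any
implementation.

## The synthetic panel

The empirical side of the model is a prefecture-by-day mobility panel.
`assemble_panel()` builds one with the study's structure:

* **Schedule.** The packaged fixture transcribes the printed Japanese
  declaration schedule: 47 prefectures, first declarations April–May
  2020, up to a fourth round in summer 2021; episodes still in force at
  the end of the analysis window (31 August 2021) carry their printed
  later end date and a `truncated` flag, and dummies are clipped to the
  window. Declaration dummies are 1 on both the declaration and the lift
  date (inclusive reading of the printed bounds; configurable).
  Over the full window the panel is $47 \times 518 = 24{,}346$ rows.
  `make_synthetic_schedule()` compresses the same four-round pattern
  into arbitrary windows (round-reach probabilities mirroring the real
  counts 47/21/19/8) so short simulation panels still identify every
  declaration number.
* **Covariates.** Zero-inflated lognormal precipitation (mm), seasonal
  sinusoid + unit offset temperature (°C), lognormal wind speed (m/s), a
  nonnegative log-AR(1) wave process with seasonal forcing for daily
  positives, synthetic prefecture populations, and holiday flags from
  the packaged calendar. The unofficial-holiday list is an approximation
  (year-end/New Year and Obon spans) and is flagged as such.
* **Disturbances.** Each mobility category receives an independent
  surface $\varepsilon_{it} = \alpha_i + \nu_{it}$ with
  $\alpha_i \sim N(0, \sigma_\alpha^2)$,
  $\nu_t = (I - \rho W)^{-1} \eta_t$ and
  $\eta_t = \psi \eta_{t-1} + e_t$, started from the AR(1) stationary
  distribution (a burn-in initialization is available) so that the
  simulated process matches the estimator's stationarity assumption.
  Innovations are Gaussian; a scaled-t switch exists for robustness
  experiments only.

Generator defaults, chosen once on the mobility-fraction scale:
$\sigma_e = 0.02$ (2% daily idiosyncratic noise), $\psi = 0.5$,
$\sigma_\alpha = 0.05$ (persistent prefecture heterogeneity),
$\rho = 0.3$ on a row-normalized ring. The ring (or lattice) topology is
a deliberate stylization: the study's real weight matrix is not
documented, and real prefecture contiguity is out of scope. True
declaration effects default to the habituation pattern of the fitted
going-out regressions — for retail, strictly shrinking negative effects
$(-0.2009, -0.0644, -0.0605, -0.0088)$ across the four declarations.

What the generator does **not** emulate: epidemiological feedback from
mobility to cases, real geography, measurement artifacts of the
mobility reports, or the pre-pandemic baseline construction. Passing
recovery tests therefore validate the estimators under the model's own
assumptions; they are not evidence about the real downloads, whose
analysis is expressly not a test surface here (readers for the public
CSV formats are provided).

## Variable construction

`prepare_panel()` implements the regression recipe on raw series, per
prefecture and without leakage across units: 7-day trailing moving
average of each mobility category (leading 6 days marked missing;
listwise deletion optional at estimation), precipitation and wind speed
log-converted against the all-prefecture mean as
$\ln\{(v + 1)/(\bar v + 1)\}$ — the offset keeps zero-rain days finite
and the value equal to the mean maps to 0; the offset-free log ratio is
available — temperature z-scored, and positives scaled per 1,000
inhabitants, smoothed over 7 days and lagged one day (lag and scaling
commute, the order is immaterial). The generator's own regressors use a
partial left-edge window instead of missing values so generated panels
stay rectangular; the strict marking rules apply to raw data.

## Estimators

**Within fixed effects.** `fit_within_fe()` demeans outcome and
regressors within prefecture and solves least squares, numerically
identical (and oracle-tested to $10^{-10}$) to least squares on unit
dummies. Covariance is the cluster sandwich
$(X'X)^{-1}\bigl(\sum_g X_g' \hat u_g \hat u_g' X_g\bigr)(X'X)^{-1}$
scaled by $\frac{G}{G-1}\frac{N-1}{N-K}$, clusters at the prefecture
level; the small-sample factor follows the common CR1 convention ($K$
counts the slope columns, not the absorbed effects). P-values are
two-sided normal.

**Spatial error with AR(1).** The random-effects model
$y_t = X_t\beta + \alpha + \nu_t$, $\nu_t = \rho W \nu_t + \eta_t$,
$\eta_t = \psi\eta_{t-1} + e_t$ is estimated by Gaussian maximum
likelihood — the model class names no estimator, and ML was chosen over
GMM because its objective can be verified against a brute-force dense
likelihood. The stacked covariance
$\sigma_\alpha^2 (J_T \otimes I_n) + \tfrac{\sigma_e^2}{1-\psi^2}
(P_\psi \otimes (B'B)^{-1})$, $B = I - \rho W$, is never formed densely:
a Prais–Winsten transform in time and multiplication by $B$ in space
whiten the spatial–serial part exactly, leaving a rank-$n$ random-effect
correction handled by the Woodbury identity, so one likelihood
evaluation costs $O(Tn^2 + n^3)$. $\beta$ is profiled by inner GLS and
$\sigma_e^2$ concentrated analytically; the bounded quasi-Newton search
runs over $(\rho, \psi, \log\theta)$ with
$\theta = \sigma_\alpha^2/\sigma_e^2$, from several moment-based starts.
An all-zero $W$ leaves $\rho$ unidentified and is refused with a
diagnostic rather than returning an arbitrary value. Standard errors
for $(\rho, \psi)$ come from the numerical Hessian of the concentrated
likelihood; those for $\beta$ from the GLS covariance at the optimum.

The two treatments of the unit effect differ on purpose: the baseline
regression absorbs prefecture effects as fixed, the spatiotemporal model
treats them as random — both estimators are retained as distinct
surfaces, mirroring the two model statements.

## Simulation studies: problem sizes

The packaged studies run at desk scale, chosen as the smallest sizes at
which the checked properties are clearly resolved: estimator-oracle
agreement on $10 \times 20$ panels and dense-likelihood agreement at
$n \le 3$, $T \le 4$; declaration-effect recovery on $n = 47$, $T = 200$
panels over 100 disturbance redraws (schedule and covariate surface held
fixed — conditional-on-design inference); spatial ML recovery at
$n = 20$, $T = 100$ over 50 replicates; and the size study of the
cluster-robust test at $n = 47$, $T = 150$ over 200 replicates. The
recovery studies redraw only the disturbance surface between replicates;
all randomness descends from a single seed.

One caveat the recovery study makes explicit: the true second and third
declaration effects differ by only $0.0039$ while their estimates carry
standard errors near $0.002$ at this scale (the study's own reported
standard errors for these coefficients are larger still), so resolving
that pair's strict order in 95 of 100 replicates is beyond the design's
statistical resolution; the observed rate is around 85–90%. The other
pairs are resolved essentially always.

## Limitations

The package estimates associations in synthetic data built from its own
model; nothing here identifies causal effects, and no claims transfer to
the real mobility downloads without rerunning on them. Cluster-robust
standard errors account for arbitrary within-prefecture correlation but
not for cross-prefecture spatial correlation, which is why the
spatiotemporal ML model exists alongside; with spatial correlation in
the generator the size of the clustered test drifts mildly above
nominal. The fourth declaration touches few prefectures, so its
coefficient is imprecise in any design mirroring the real schedule.
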