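---
title: "Modelling risk-factor time paths in type 2 diabetes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling risk-factor time paths in type 2 diabetes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Health-economic simulation models of type 2 diabetes need two ingredients:
equations that translate risk-factor levels into complications, and
equations that say where the risk factors themselves are heading over a
simulated lifetime. riskpath implements the second ingredient: a
patient-level annual-cycle engine for seven continuous risk factors, four
absorbing comorbid conditions and kidney function, together with the
estimation machinery to refit every equation from longitudinal panel data
and the validation machinery to judge the fit.

## The model

### Continuous risk factors

Each of HDL-C (mmol/l), LDL-C (mmol/l), systolic blood pressure (mmHg),
HbA1c (%), haemoglobin (g/dl), heart rate (bpm) and BMI (kg/m²) follows a
first-order dynamic panel equation

$$y_{it} = \phi_0 + \phi_1 y_{i,t-1} + \phi_2 y_{i0} + \phi_3\,
\mathrm{female}_i + \phi_4(\mathrm{ethnicity}_i) + \phi_5\,
\mathrm{age}_i + \phi_6 \ln(\mathrm{duration}_{it}) + \mu_i +
\varepsilon_{it},$$

where $y_{i0}$ is the patient's first recorded value, age is age at
randomisation, duration is years since diabetes diagnosis, $\mu_i$ is a
time-invariant patient effect and $\varepsilon_{it}$ an annual
disturbance. Because $|\phi_1| < 1$, each equation is mean-reverting: a
perturbation decays geometrically at rate $\phi_1$ towards a long-run
level set by the patient's first value and demographics
(`long_run_mean()`). The shipped coefficients (`default_bundle()`) carry
the published point estimates at their printed three-decimal precision;
the disturbance variances were not published, so `resid_sd` and `re_sd`
default to 0 and the default simulation is an expected-value projection.
Refitting on data fills both in.

### Absorbing conditions

Atrial fibrillation, micro/macroalbuminuria, peripheral vascular disease
and the crossing of eGFR below 60 ml/min/1.73m² are modelled as
Weibull proportional hazards on the *diabetes-duration* time scale:
$h(t) = \gamma t^{\gamma - 1} e^{x'\beta}$. Using duration rather than
study time lets patients who enter observation at different durations be
pooled on one axis, in the manner of a period life table. Each annual
cycle converts the fitted hazard into a conditional probability

$$p_t = 1 - \exp\{H(t) - H(t+1)\},$$

the standard discrete-cycle conversion in this model family; covariates
are held at their start-of-year (lagged) values across the interval. A
uniform draw against $p_t$ flips the condition flag; flags never revert.
States are absorbing by assumption — the equations describe diagnosis,
not remission.

### Two-part eGFR

Downstream complication equations treat eGFR 60 as a clinical knot, so
the share of patients below 60 matters as much as the mean. eGFR is
therefore simulated in two parts: the Weibull crossing equation decides
*whether* a patient is below 60 this year (absorbing), and two
censored-normal (Tobit) value equations — one per regime, with limits
(0, 60) and (60, ∞) — produce the continuous value. In deterministic
mode the value is the truncated-normal mean; in stochastic mode it is an
inversion draw from the truncated normal. Either way the value lands
strictly on the correct side of 60, which is asserted as a type invariant.
The published "standard error of the forecast" (11.888 / 13.839) is
treated as the total draw SD. A configurable physiological cap (default
200) bounds the open upper regime.

## The annual cycle

Within a cycle the order is: condition equations first (they must see
genuinely lagged risk factors), then the continuous updates, then the
eGFR value model. All three read the *incoming* state, so the
within-cycle order has no numerical effect; `ln(duration)` is evaluated
at the year being predicted. No mortality is modelled — trajectories are
conditional on survival, and a cohort of $n$ patients always yields
$n \times \text{horizon}$ records. This is stated prominently because
feeding these trajectories into a costing model without an external
mortality model would misstate life-years.

Random-number discipline: each patient owns a seeded substream (derived
from the run seed and the patient id), laid out in fixed blocks per
equation. Permuting the cohort permutes output rows only, and identical
`(bundle, cohort, config)` runs are byte-identical on export.

### Interventions

An intervention is a one-off additive shift (e.g. HbA1c −0.5%) applied to
the **year-1 values** and to the first-recorded store. This mirrors how
decision modellers use such equations: the treatment effect sets the
first post-treatment value, and the background equations take over from
year 2. The year-$k$ arm difference then follows the recursion
$D_1 = \delta$, $D_k = \phi_1 D_{k-1} + \phi_2 \delta$ — a
$\phi_1$-geometric transient plus a $\phi_2$-persistent component with
limit $\delta\,\phi_2/(1-\phi_1)$. (A shift applied *before* the first
update would produce a year-1 effect of $(\phi_1{+}\phi_2)\delta$, which
contradicts how first-year treatment effects are reported; we use the
convention above.) `locf_bundle()` supplies the
last-observation-carried-forward comparator: identity dynamics, zero
hazards.

### Expected versus stochastic mode

Deterministic mode records per-year event probabilities without flipping
flags; accumulating them as $1-\prod_t(1-p_t)$ reproduces what
Monte-Carlo binarization of the same probabilities converges to, and the
test suite checks this at $10^5$ patients. The `value_draws` switch
exists because the equivalence is a property of the *probability-to-event
conversion*, not of the full stochastic model: when stochastic eGFR
draws (SD ≈ 13.8) feed the crossing equation's lagged eGFR, the convex
hazard makes the mean of the probability exceed the probability at the
mean (Jensen's inequality, roughly +7% on the crossing hazard), so full
stochastic incidence legitimately sits above the expected-mode curve for
that one outcome. Setting `value_draws = FALSE` isolates the
binarization channel.

## Estimation

* `fit_dynamic_panel()` — random-intercept maximum likelihood
  (`lme4::lmer`) with the lag and the first recorded value as regressors.
  Treating the lag as exogenous incurs the classical small-T dynamic-panel
  bias; with six annual waves and the baseline value in the regressor set
  the bias is well inside sampling error at trial sample sizes (the
  recovery tests check every coefficient against 3 reported SEs), and it
  matches how such equations are estimated in practice. R² is reported as
  the squared correlation of fitted and observed values.
* `tobit_mle()` / `fit_tobit()` — pooled censored-normal likelihood
  (limit observations contribute probability mass, interior ones density),
  maximized with BFGS; `survival::survreg` on interval-censored data is
  the independent cross-check in the tests. Note a subtlety checked by
  the tests: the *simulator's* regime values are truncated draws (no
  boundary mass, regime chosen by state), so refitting a Tobit on
  two-part-simulated panels does not recover the generating betas; the
  censored-likelihood contract is demonstrated on data whose observation
  process is genuinely censored at the limits.
* `ph_mle()` / `fit_parametric_ph()` — left-truncated parametric PH
  likelihood $\sum_i d_i \log h(t_{exit,i}) + H(t_{entry,i}) -
  H(t_{exit,i})$ over counting-process rows, for Weibull, exponential and
  Gompertz families with directly comparable AICs. Left truncation is
  mandatory here: cohort members enter ~16 years after diagnosis, and
  ignoring delayed entry would wildly overstate early hazards.
  Cluster-robust (sandwich) standard errors by subject are the default.
  `flexsurv::flexsurvreg` is the independent cross-check.
* `backwards_stepwise()` — removes the largest Wald p until all
  $p < \alpha$ (default 0.05), with a deterministic tie-break (the
  later-declared covariate goes first). Operating characteristics —
  noise retained at the nominal rate, a 10-SE signal always kept — are
  verified over 200 simulated replicates.
* `cox_snell_residuals()` — $\hat H$ increments over each subject's
  observed exposure; under a correct model these behave as censored
  unit-exponential samples (Nelson–Aalen slope ≈ 1).

## Synthetic data

`generate_cohort()` draws baseline cohorts anchored to the trial-summary
level: age 64 ± 8, lognormal duration with mean ≈ 16 years, 35% female, a
white-majority ethnicity mix, 12% smokers. The baseline risk-factor
means, SDs and the mild correlation structure are *generator choices* at
clinically plausible values (e.g. HbA1c 7.5 ± 1.2%, SBP 135 ± 16 mmHg) —
they are not transcribed from any trial baseline table, and all are
overridable. `generate_panel()` runs the simulation engine in stochastic
mode and overlays an observation process: yearly visits up to six years
(the trials' follow-up length), non-informative annual dropout (default
3%), optional measurement noise and missingness, and continuous
condition-onset times placed within the onset year by inverting the
within-year conditional survivor. The plausibility ranges used by
`preprocess_panel()` are documented package defaults, standing in for a
cleaning protocol that is not public.

What passing tests on these panels shows: the estimation and validation
machinery is internally coherent — parameters that generated the data are
recovered, and predictions agree with data simulated from the same
equations. What it cannot show: that the published equations describe any
particular real cohort, that trial missingness patterns are reproduced,
or that per-factor eligible sample sizes match the source analyses.

## Numerical choices

* Duration is floored at 0.5 years before logging, so `ln(duration)`
  stays finite near diagnosis; with entry durations around 16 years the
  floor is inert for realistic inputs.
* Truncated-normal draws use inversion of the normal CDF; when the
  truncation interval carries essentially no mass (e.g. σ → 0 against a
  far limit), the value collapses to the clamped mean rather than
  returning non-finite values.
* `H(0) = 0` by convention, so newly diagnosed patients are handled
  without special cases; zero-hazard comparators use a constant of
  −1000, which underflows `exp()` to exactly 0.
* Optimizers: BFGS with tight relative tolerance (1e−12); every fitted
  likelihood is asserted to be at least the likelihood at the generating
  parameters.
* Kaplan–Meier comparisons condition both curves on being event-free at
  the first integer duration whose risk set reaches `min_risk`
  (default 50): with delayed entry, the product-limit estimate over the
  sparse earliest risk sets is dominated by a handful of patients, and a
  random early deficit or excess would otherwise propagate down the
  whole cumulative curve. The model curve pools fitted cumulative-hazard
  increments over the same realized person-time, split at integer
  boundaries (occurrence–exposure pooling), so observation and
  prediction share both the time axis and the at-risk population. Even
  so, the observed band is a pointwise 95% interval: over ~30 correlated
  duration bins a few nominal misses are expected, which is why the
  self-consistency checks assert near-complete rather than literal 100%
  coverage.
* Quintile calibration assigns ties to the lower quintile via min-rank;
  with $n$ divisible by 5 and distinct values the strata are exactly
  balanced.

## Problem sizes in the test suite

The suite exercises the engines at the scales the contracts are stated
for: $10^5$ patients for simulator-consistency checks, $10^6$ draws for
truncated-normal moments, $n = 5{,}000 \times 6$ years for
dynamic-equation recovery, $n = 20{,}000$ with 40% late entry and ~70%
censoring for the survival recovery and the 100-replicate AIC selection
study, $10^4$ patients for validation self-consistency, and 200
replicates for stepwise operating characteristics. The full suite runs
in a few minutes on one CPU.

## Known limitations

* Coefficients are the printed three-decimal values; full-precision
  values were never published.
* No mortality, no treatment-effect modelling inside the equations (the
  trials' allocation arms were deliberately excluded as covariates), no
  competing-risk correction between the four conditions.
* White-blood-cell count and smoking trajectories are out of scope, as
  are trial-specific and treatment-arm coefficient sets.
* The dynamic-panel estimator accepts Nickell-type bias by design; users
  refitting on very short panels (2–3 waves) should expect upward bias
  in $\phi_1$.
* Downstream outcomes (complication events, QALYs, costs) belong to the
  external models these equations feed and are not computed here.
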