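---
title: "Methods: lifetime Markov cost-effectiveness modelling of localised prostate cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lifetime Markov cost-effectiveness modelling of localised prostate cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcmarkov)
```

## The decision problem and the model

`pcmarkov` compares three randomised management strategies for clinically
localised prostate cancer — active monitoring (AM), radical prostatectomy
(RP) and radical radiotherapy (RT) — on lifetime discounted costs and
QALYs, extrapolated from trial-like patient-level data with roughly
ten-year follow-up.

The cohort model has five states: *stable* (managed disease under the
randomised strategy), *local progression*, *metastatic disease*, *death
from prostate cancer* and *death from other causes*. The whole cohort
starts in the stable state and moves at annual intervals, reflecting the
slow natural history of the disease. Structural assumptions:

* prostate-cancer death is only possible from the metastatic state (local
  disease rarely kills directly);
* both death states are absorbing and no backward transitions exist;
* men may reach metastasis either through local progression or directly
  from the stable state. The direct edge is included by default because
  trials record progression and metastasis as separate endpoints and some
  men present with metastases without a recorded local progression;
  `fit_all_transitions()` estimates it from exactly those men, and the
  generator has a switch (`allow_direct_metastasis = FALSE`) for the
  strictly sequential structure;
* treatment changes (e.g. AM men moving to radical treatment) are not a
  separate state: their cost consequences are folded into the observed
  state-by-strategy annual costs, which is how trial cost data are
  collated.

## Transition hazards

Each disease edge carries a parametric proportional-hazards model with
cumulative hazard

\[ H(t) = (t/\sigma)^\kappa \quad\text{(Weibull)},\qquad
   H(t) = \lambda t \quad\text{(exponential, } \kappa = 1,\
   \lambda = 1/\sigma\text{)}, \]

fitted to right-censored durations by maximum likelihood
(`survival::survreg` supplies the fits; the package converts its
accelerated-failure-time parameterisation to the form above and keeps the
estimation-scale covariance matrix). The annual transition probability
conditional on being at risk at cycle \(t\) is

\[ p(t) = 1 - \exp\{H(t) - H(t+1)\}, \]

constant for the exponential, increasing in \(t\) for \(\kappa > 1\). The
Weibull parameterisation is stated explicitly so every numeric test is
unambiguous; at \(\kappa = 1\) Weibull and exponential probabilities agree
to 1e-10 (tested).

**Family selection.** The model family for each edge is chosen by AIC
between the two candidates fitted to identical data, with ties (and equal
log-likelihoods) resolved to the exponential, which has one fewer
parameter and is nested in the Weibull. AIC is the conventional criterion
when "best fit" is otherwise unspecified; note that under an exponential
truth AIC still selects the Weibull with asymptotic probability
\(P(\chi^2_1 > 2) \approx 0.157\), which the test suite checks rather than
pretending selection is near-certain.

**Arm effects.** The randomised arm enters as a covariate on the two
stable-state exits only (fitted jointly, so the PSA respects the
correlation between the baseline and arm coefficients); hazards after
leaving the stable state are shared across arms. `hazard_ratio()` converts
the AFT coefficient to a hazard ratio, \(\mathrm{HR} = e^{-\kappa\beta}\).
Subgroup analyses (`stratified_analysis()`) refit everything within the
stratum instead.

**Edge derivation from trial columns.** A patient-year is attributed to
the state occupied at the start of the year (transition dates within a
year are not modelled). Time at risk of leaving the stable state ends at
the first of progression, direct metastasis, or censoring; progression and
direct metastasis are competing events on that clock. Men who progress
contribute `t_met − t_prog` to the progression→metastasis edge; men with
metastases contribute `t_pcdeath − t_met` to the metastasis→death edge.

## Other-cause mortality

Age-specific other-cause death probabilities come from a national male
life table with prostate-cancer (ICD-10 C61) deaths removed by the
proportional-hazards (Chiang-style) cause-deletion formula

\[ q_{other} = 1 - (1-q_{all})^{(d_{all}-d_{C61})/d_{all}}, \]

chosen over simple subtraction because it guarantees
\(0 \le q_{other} \le q_{all}\). The package ships a **synthetic**
UK-2014-shaped table (`default_life_table()`, ages 50–100; Gompertz
all-cause hazard `q = 0.003·exp(0.094·(age−50))` capped at 0.99, C61 share
of deaths `0.02 + 0.04·exp(−((age−80)/12)²)`). It reproduces the
qualitative behaviour the model needs — other-cause mortality rising
steeply and monotonically with age — but is not ONS data, so absolute
life-expectancy figures are illustrative.

Within a cycle, other-cause death takes precedence: \(q_{other}\) at the
cohort's current age is applied to every living state and disease
transition probabilities are scaled by \(1-q_{other}\). This is standard
cohort-model practice and keeps rows stochastic by construction.

## Values, discounting and decision metrics

State utilities (EQ-5D-3L index units) are averaged over all patient-years
in a state, pooled across strategies — the strategy effect on quality of
life is then carried entirely by the proportions of men in each state.
Missing annual scores are imputed as the mean of the nearest observed
prior and following years (boundary gaps carry the single nearest value);
a fully missing series is an error. Annual costs are averaged within
(state, strategy); the year of death is pooled across strategies into a
shared last-year-of-life cost, applied once to new entrants to either
death state. Death states have utility 0 and recurring cost 0 by
definition.

Costs and QALYs accrued during cycle \(t\) are discounted by
\((1+r)^{-t}\) (cycle-start convention) at \(r = 3.5\%\), the UK NICE
reference case; all monetary values are GBP at 2014–15 prices with no
inflation machinery. The default horizon is age 100 — occupancy beyond is
negligible at these mortality levels — and both horizon and starting age
(default 50) are arguments.

**Half-cycle correction** (default on) averages start- and end-of-cycle
occupancy for the occupancy-based payoffs, which for time-constant payoffs
equals the standard first/last half-cycle adjustment; last-year-of-life
costs are flows attached to death entrants and are never half-cycle
corrected. The flag exists because the life-table annuity closed form used
in testing, \(\sum_t (1+r)^{-t} \prod_{s<t}(1-q_{other}(s))\), is the
uncorrected quantity.

**Decision metrics.** \( \mathrm{NMB} = \mathrm{QALYs}\times\lambda -
\mathrm{cost}\) at threshold \(\lambda\) (default £20,000/QALY; CEACs
sweep £0–50,000 by default, comfortably covering the £20–30,000 range
decision-makers use). Strategies are ranked by NMB with exact ties broken
by lower cost, then label order; when percentile CIs are available and the
best strategy's interval overlaps another's, the result is flagged as weak
evidence.

## Probabilistic sensitivity analysis

All inputs are drawn jointly each iteration:

* survival coefficients — multivariate normal on the estimation scale
  (log scale, log shape, AFT arm coefficients) with the fit covariance;
* utilities — beta, moment-matched from the estimated mean and standard
  error (a mean outside (0,1), legal for EQ-5D, falls back to a normal
  truncated to [−0.594, 1]);
* costs — gamma, moment-matched; zero-SE parameters stay at their point
  estimates, and a fully degenerate PSA warns and reproduces the
  deterministic result exactly (tested).

One master seed generates a table of per-iteration seeds, so iteration
\(i\) is reproducible in isolation and results do not depend on execution
order. Percentile CIs use linear interpolation between order statistics
(R quantile type 7) — fixed so CI tests are exact. CEAC ties split equally
across the tied strategies, so probabilities sum to one at every threshold
by construction.

Two summaries of the point NMB are possible from a PSA — the mean of the
per-draw NMBs (default, `point = "mean_nmb"`) or the NMB of the mean cost
and QALYs — and results grids combine deterministic mean costs/QALYs with
the probabilistic NMB and its CI, as cost-effectiveness tables
conventionally do.

## The synthetic-data generator

`generate_cohort()` emulates the trial structure the estimation stage
assumes: per man, competing Weibull times from the stable state to
progression and to metastasis (arm and risk-group hazard ratios applied
multiplicatively), an exponential progression→metastasis time, an
exponential metastasis→death time, other-cause death sampled year-by-year
from the life table (uniform within the year), and administrative
censoring uniform on median ± 2 years — the accrual pattern behind a
"median 10-year follow-up" is rarely reported, and any choice preserving
that median serves testing. Annual utilities and costs are Gaussian around
the occupied state's mean (utilities truncated to the EQ-5D-3L index range
[−0.594, 1], costs at 0), with the year of death drawn from the shared
terminal cost, and utilities missing completely at random with probability
0.1 per year.

Defaults were chosen once to match the study conditions of a three-arm
localised prostate cancer trial: 545 men per arm; entry ages uniform on
50–69; AM stable→progression Weibull(κ = 1.3, σ = 25) (≈26% progress by 10
years) and stable→metastasis Weibull(1.3, 85) (≈6% by 10 years); hazard
ratio 0.45 for both radical arms on the stable-state exits (halving the
metastasis rate); progression→metastasis rate 0.10/year; metastatic
survival exponential at 0.25/year (median ≈ 2.8 years); utilities
stable/progression/metastatic 0.80/0.75/0.65 (SD 0.15/0.18/0.10); annual
costs AM/RP/RT £550/£450/£500 in stable, £1,200 in progression, £5,000 in
metastatic (SD 20%), terminal cost £3,000 (SD £600). D'Amico
intermediate/high risk has prevalence 0.44 with hazard ratio 2 on the
stable-state exits, and Grade group ≥2 is correlated with it (prevalence
0.45 within intermediate/high, 0.05 within low), so stratified analyses
have real signal.

**What passing tests do and do not show.** The generator produces exactly
the parametric world the estimator assumes, so recovery tests demonstrate
the pipeline's internal correctness — not robustness to the ways real
trial data deviate: informative censoring, utilities that dip around
treatment and recover, cost skew beyond a truncated normal, risk-dependent
treatment selection, or mid-year transitions. Absolute results on
synthetic data are therefore illustrative; the pipeline's value on real
data rests on the same estimators' standard behaviour under those
violations.

## Numerical choices and degenerate inputs

* Occupancy is checked to sum to 1 within 1e-10 each cycle (violations
  raise an error naming the failing input; in a PSA the iteration index is
  reported).
* A zero-hazard edge is represented exactly (infinite scale, p = 0), not
  by a small rate.
* Exponential fits need ≥1 event, Weibull ≥2; all-censored data raise a
  "no events" error. `survreg` runs with `maxiter = 500`; non-convergence
  or NA coefficients raise an error.
* Family selection refuses models fitted to different data (a hash of n,
  event count and total time is compared).
* Stable-state exit probabilities are validated to sum ≤ 1 within a cycle
  before the matrix is built.
* Cohort starting age defaults to 50 everywhere; the age-band analyses in
  `scripts/acceptance.R` start the cohort at the band's representative age
  (50 / 65), since a single starting age cannot reproduce the large QALY
  gap between age subgroups that lifetime models show.

## Problem sizes used in tests and scripts

The shipped suite runs cohorts of 100–3,334 men per arm (the larger sizes
for parameter-recovery checks at n = 10,000), PSAs of 50–200 iterations
inside tests, and the acceptance script runs the full default cohort
(1,635 men) with a 10,000-iteration PSA — the package's reference PSA
size, matching standard practice for stable CEAC estimates.

## Known limitations

* No tunnel states: hazards after progression depend on time since
  progression only through the fitted exponential's memorylessness.
* No adverse-event states (urinary/bowel/sexual dysfunction); EQ-5D-3L
  utilities are assumed to carry whatever quality-of-life impact exists.
* Utilities and costs observed during follow-up are assumed to persist for
  life within a state.
* The cohort model is deterministic at the population level; individual
  heterogeneity enters only through subgroup stratification.
* The shipped life table is synthetic; analyses intended for decisions
  should substitute the relevant national table via `load_life_table()`.
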