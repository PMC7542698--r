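# pcmarkov

Lifetime cost-effectiveness modelling of management strategies for
clinically localised prostate cancer.

Localised prostate cancer progresses slowly, and the three mainstream
management strategies — active monitoring (AM), radical prostatectomy (RP)
and radical radiotherapy (RT) — trade off up-front treatment burden against
long-run risks of progression and metastasis. Trial follow-up (typically a
median of ~10 years) is far shorter than the remaining lifetime of men
diagnosed in their 50s and 60s, so decision-makers need a model that
extrapolates trial evidence over a lifetime and expresses the result as
cost per quality-adjusted life year (QALY). `pcmarkov` is for health
economists and HTA analysts who want that full pipeline — from censored
patient-level trial data to cost-effectiveness acceptability curves — as
tested, scriptable R functions rather than a spreadsheet.

## The model

A five-state annual-cycle Markov cohort model with states

```
stable  →  progression  →  metastatic  →  death (prostate cancer)
   \__________↑___________________↓
    \______________→  death (other causes, from any living state)
```

* **Transitions.** Each disease edge carries a parametric proportional
  hazards model fitted to censored patient-level data by maximum
  likelihood: Weibull with cumulative hazard `H(t) = (t/σ)^κ`, or
  exponential (`κ = 1`, rate `λ = 1/σ`); the family is chosen per edge by
  AIC. The annual transition probability at cycle `t` is
  `p(t) = 1 − exp{H(t) − H(t+1)}`. The randomised arm enters as a hazard
  ratio on the two stable-state exits.
* **Other-cause mortality** comes from a national life table with
  prostate-cancer (ICD-10 C61) deaths removed:
  `q_other = 1 − (1 − q_all)^((d_all − d_C61)/d_all)`. Within a cycle it is
  applied first; disease transitions are scaled by `1 − q_other`.
  Prostate-cancer death is only reachable from the metastatic state.
* **Values.** EQ-5D-3L state utilities are pooled across strategies
  (missing annual scores imputed from adjacent years); annual NHS costs
  (GBP, 2014–15 prices) are state- and strategy-specific, plus a shared
  last-year-of-life cost. Costs and QALYs are discounted at 3.5% per year
  and accumulated from age 50 to age 100 with a half-cycle correction.
* **Decision metrics.** Net monetary benefit `NMB = QALYs × λ − cost` at a
  willingness-to-pay threshold `λ` (default £20,000/QALY); probabilistic
  sensitivity analysis (PSA) draws all inputs jointly (survival
  coefficients: multivariate normal on the estimation scale; utilities:
  beta; costs: gamma), giving percentile CIs and cost-effectiveness
  acceptability curves (CEACs).

A synthetic-data module generates trial-like cohorts with exactly this
statistical structure (competing Weibull stable-state exits, exponential
onward times, life-table other-cause death, ~10-year administrative
censoring, state-dependent noisy annual utilities and costs), so the whole
pipeline — including parameter recovery — is testable without any
restricted trial data.

## Worked example

```r
library(pcmarkov)

cfg <- generator_config(n_per_arm = 300, seed = 2024)
cohort <- generate_cohort(cfg)
cohort
#> <pc_trial_data> 900 patients (AM: 300, RP: 300, RT: 300)
#>   events: 170 progression, 103 metastasis, 57 PC death, 116 other death

cea <- evaluate_strategies(cohort, psa = psa_config(n_iterations = 1000, seed = 7))
cea
#> <pc_cea> threshold GBP 20,000 per QALY
#>  strategy mean_cost mean_qaly    nmb   nmb_lo   nmb_hi
#>        AM     18291     11.50 210820 197574.2 222319.0
#>        RP     13895     13.05 245626 231877.0 255787.4
#>        RT     14588     13.08 245545 231322.5 255811.4
#> most cost-effective strategy: RP
#> note: 95% CIs overlap; evidence of a difference is weak
```

Reading the output: `mean_cost` and `mean_qaly` are deterministic
discounted lifetime totals per cohort member (e.g. active monitoring costs
£18,291 and yields 11.50 QALYs over a lifetime here — more expensive and
less effective than the radical strategies because more men reach the
costly metastatic state); `nmb` is the probabilistic net monetary benefit
at £20,000/QALY with its 95% percentile CI. RP has the greatest NMB, but
its CI overlaps RT's, so the evidence of a difference between the radical
strategies is weak — the CEAC in `cea$ceac` quantifies this as the
probability each strategy is the most cost-effective at each threshold.

Subgroup (intention-to-treat) analyses refit everything within a stratum:

```r
stratified_analysis(cohort, by = "damico")
```

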