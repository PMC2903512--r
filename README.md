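# cidpce

A cohort Markov model comparing intravenous immunoglobulin (IVIG) with
corticosteroids for chronic inflammatory demyelinating polyneuropathy
(CIDP), from a Canadian public-payer perspective, in 2008 Canadian dollars.

CIDP is a chronic immune-mediated peripheral neuropathy. IVIG improves
symptoms in randomized trials but is dosed per kilogram of body weight and
costs tens of thousands of dollars per patient-year; corticosteroids cost a
few dollars per cycle but expose patients to fracture, diabetes, cataract,
glaucoma and serious infection. The package is for health-economic analysts
who want this trade-off as tested, reusable code rather than a spreadsheet:
every model input is a parameter, every structural switch is a
configuration field, and every published summary is a reproducible function
call.

## The model in brief

* **State-transition cohort model**, 12-week cycles, 5-year basecase horizon
  (22 cycles), cohort aged 54 and weighing 75 kg at entry. IVIG patients
  respond with pooled probability 0.473 and relapse at 6.5% per cycle;
  non-responders and relapsers move to corticosteroids. Steroid-treated
  patients face five adverse events (AEs), each with a first-year tunnel,
  mortality increment, disutility and cost; death is absorbing.
* **Effectiveness** is measured in quality-adjusted life years (QALYs):
  age-banded general-population utility, +0.12 on effective IVIG, minus AE
  disutilities. Costs and QALYs are discounted at 5%/year,
  `(1+r)^(-(t-1)·12/52)` per cycle.
* **Decision statistic**: the incremental cost-utility ratio
  ICUR = (Cost_IVIG − Cost_steroid) / (QALY_IVIG − QALY_steroid),
  plus one-way scenarios and a 1000-draw probabilistic sensitivity analysis
  (PSA) summarized as the cost-effectiveness acceptability curve
  CEAC(λ) = P(λ·ΔQALY − ΔCost > 0).
* **Meta-analysis**: the response probability is a DerSimonian–Laird
  random-effects pool of six trial arms on the raw-proportion scale with
  inverse-variance weights 1/(v_i + τ²), v_i = p_i(1−p_i)/n_i.

See `vignettes/model-methods.Rmd` for the full model description,
assumptions, and design decisions.

## Worked example

```r
library(cidpce)

# pooled IVIG response rate across the six trials
pool_response_rate(default_trials())
#> <cidp_pooled> 47.3% (95% CI 36.1%, 58.5%), tau2 = 0.0079, I2 = 42.9%
#>   Zinman (2005)      w = 0.08
#>   Thompson (1996)    w = 0.08
#>   Mendell (2001)     w = 0.20
#>   Hughes (2008)      w = 0.27
#>   Vermuelen (1993)   w = 0.16
#>   Hahn (1996)        w = 0.21

# deterministic basecase: both arms, 22 cycles
run_basecase()
#> <cidp_ce_result>  (discounted totals)
#>   corticosteroids: $1,535.26, 3.591 QALYs
#>   IVIG:            $118,697, 3.764 QALYs
#>   incremental:     $117,161.8, 0.173 QALYs
#>   ICUR: $676,434 per QALY gained
```

IVIG buys 0.173 extra QALYs over five years at an extra cost of ~$117k —
about $676k per QALY gained, far above conventional willingness-to-pay
thresholds. (The published analysis this model re-implements reports
$121,869, 0.177 and $687,287; the remaining 2–4% gap reflects unstated
structural choices and is characterized in the vignette.) A single
trace is also inspectable:

```r
run_cohort(model_config(arm = "IVIG"), default_parameters())
#> <cidp_trace> IVIG arm, 22 cycles (age 54.0-58.8)
#>   discounted totals: $118697.04, 3.7645 QALYs (undiscounted $127797.16, 4.2111)
#>   surviving at end: 0.9756
```

Scenario and probabilistic analyses:

```r
run_owsa()                       # 28 published scenarios -> inc cost/QALY/ICUR
psa <- run_psa(n_sims = 1000, seed = 1)
prob_cost_effective(psa, c(5e4, 67e4))
#> [1] 0.000 0.493    # <1% cost-effective at $50k/QALY; ~50% at $670k/QALY
```

Or from the shell, writing CSV tables plus a reproducibility manifest:

```sh
Rscript inst/cli/cidp.R basecase --out results/
Rscript inst/cli/cidp.R psa --out results/ --n-sims 1000 --seed 1
```

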