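---
title: "Methods: a cost-utility Markov model of IVIG versus corticosteroids in CIDP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a cost-utility Markov model of IVIG versus corticosteroids in CIDP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cidpce)
```

## The decision problem

Chronic inflammatory demyelinating polyneuropathy (CIDP) is a chronic
immune-mediated peripheral neuropathy. Intravenous immunoglobulin (IVIG)
improves symptoms in randomized trials but is dosed by body weight and very
expensive; corticosteroids are cheap but carry long-run adverse-event (AE)
risk. `cidpce` implements a cohort Markov model that weighs these two
strategies in quality-adjusted life years (QALYs) and 2008 Canadian dollars
from a public-payer perspective, and reports the incremental cost-utility
ratio (ICUR), one-way scenario analyses, and a probabilistic sensitivity
analysis (PSA) summarized as cost-effectiveness acceptability curves (CEACs).

## Model structure

Cycles are 12 weeks long; the basecase horizon is 5 years, run as
`round(5 * 52 / 12) = 22` whole cycles (264 weeks, a documented <2%
truncation of the horizon). The cohort enters at age 54 weighing 75 kg.

In the IVIG arm, everyone starts in an initial treatment state (two 1 g/kg
loading doses plus maintenance doses at weeks 3, 6, 9, 12). A pooled
proportion 0.473 responds and continues maintenance IVIG; non-responders
switch to corticosteroids. Responders relapse with probability 0.065 per
cycle (the source trial's 25-week cumulative relapse of 13%, halved linearly
to the 12-week cycle — deliberately *not* the constant-hazard conversion, to
match the published rate) and relapsers switch to corticosteroids. In the
corticosteroid arm everyone starts on steroids; no responder split is made.

Steroid-treated patients face five AEs with annual probabilities (fracture
0.0098, diabetes 0.0043, cataract 0.0114, glaucoma 0.0008, serious infection
0.0035), converted to cycle scale by `1 - (1 - p)^(12/52)` and allocated
sequentially on the remaining mass in a fixed order (fracture, diabetes,
cataract, glaucoma, infection); with per-cycle AE probabilities below 0.003
the order matters only at O(p^2) ≈ 1e-5. An AE stops steroid treatment.
First-year fracture, diabetes and glaucoma effects are encoded as 4-cycle
tunnel states (1 year ≈ 4.33 cycles, truncated to 4 by the whole-cycle
engine); fracture and diabetes then carry permanent "subsequent-year"
states, glaucoma resolves, cataract waits one cycle for surgery (109-day
wait mapped to one 84-day cycle) and then carries a permanent post-surgical
state, and serious infection is a single acute cycle. Patients whose AE has
resolved and who carry no residual condition sit off treatment with no
further AE risk. Death is absorbing: background mortality from the bundled
life table applies to every alive state each cycle, and fracture/diabetes
mortality increments (annual, converted to cycle scale) plus the acute
infection case-fatality (0.018 under 65, 0.111 at 65+, applied once,
unconverted) act on survivors of background mortality.

Because a cohort model is memoryless, the engine internally expands the 13
user-facing states to 24 (tunnel sub-states, and three time-on-steroid
sub-states that carry the $51.19 / $43.57 / $39.87 drug-cost schedule;
late starters enter that schedule at its first cycle).

## Values attached to states

Utilities are unisex general-population values by age band (0.91, 0.845,
0.795, 0.78, 0.73 for 35-44 through 75+), plus 0.12 while on effective IVIG
(initial cycle and responder cycles), minus AE disutilities: age-banded
first/subsequent-year values for fracture and diabetes, 0.38 while awaiting
cataract surgery and 0.10 after, 0.061 during the glaucoma year, and full
utility loss for 2 of the 12 infection-cycle weeks. State utility is floored
at 0 but deliberately not capped at 1: the published 0.25-utility-gain
scenario only reproduces if the gain is applied uncapped. The cohort's mean
age advances 12/52 years per cycle and drives every age-band and life-table
lookup.

Costs: IVIG administration is `weight x dose x $59.19/g + 3.5 h x $32/h`
($4,551.25 basecase), giving $27,307.50 for the initial cycle and $18,205
per responder cycle. The per-cycle steroid schedule is a fixture; a
bottom-up reconstruction from pill prices and the tapering regimen
(`steroid_cost_reconstruction()`) lands within ~$10-15 and its gap is
reported rather than hidden, because the dispensing-fee count behind the
published figures is not recoverable. Fracture/diabetes annual costs are
spread at `annual x 12/52` per cycle (first-year values across the 4 tunnel
cycles, so the 4-cycle dwell accrues 48/52 of the annual total); cataract
surgery ($6,218), glaucoma work-up ($152) and the infection episode
($24,334) are charged once on the single-entry state. Costs and QALYs are
accrued on start-of-cycle state membership and discounted by
`(1 + r)^(-(t-1) x 12/52)` at 5%/year; no half-cycle correction is applied
(the source analysis does not mention one), but
`model_config(half_cycle_correction = TRUE)` switches to mean-of-boundaries
accrual.

## Meta-analysis

The initial response probability pools six trial arms (n = 8, 7, 29, 59,
15, 30; responders = 4, 3, 11, 32, 4, 19) by DerSimonian-Laird
random-effects on the *raw proportion* scale, inverse-variance weights
`1/(v_i + tau^2)` with `v_i = p_i(1 - p_i)/n_i`, and a normal-approximation
95% CI (z = 1.959964). Raw-scale pooling is a deliberate choice: it is the
only scale that reproduces the published per-study weights (0.08, 0.08,
0.20, 0.27, 0.16, 0.21) and CI (36.1%, 58.5%); logit-scale pooling is
available via `scale = "logit"` for comparison. Degenerate proportions get
a 0.5 continuity correction and a flag; a single study is returned as-is
with `tau2 = 0` and a flag.

```{r meta}
pool_response_rate(default_trials())
```

## Synthetic data: what it emulates, what it does not

The published analysis cites national life tables without printing them, so
the bundled table is a frozen Gompertz-Makeham stand-in
(`h(x) = 2e-4 + 2.78e-5 e^{0.092x}`), calibrated so the annual death
probability is ~0.004 at 54 and ~0.043 at 80 — typical of Canadian unisex
tables of the period, chosen once before any result was inspected. Varying
the Gompertz slope over 0.092-0.11 (q(80) from 0.043 to 0.068) moves the
basecase ICUR by <0.01% and even the 20-year-horizon ICUR by <0.1%, because
background mortality cancels almost exactly between arms; a green basecase
therefore does not validate the life table itself, only the model's
insensitivity to it.

`simulate_trials()` generates homogeneous or heterogeneous response trials
on the logit scale (keeping latent proportions in (0,1)) for meta-analysis
property tests — it emulates binomial sampling noise and between-study
spread, not publication bias or study-quality differences.
`perturb_parameters()` jitters every probability, utility and cost (clipped
back to their legal ranges) to stress the engine's structural invariants on
inputs other than the basecase.

## Probabilistic sensitivity analysis

Each of the 1000 second-order simulations draws one parameter set, applied
to both arms (common random parameters). Published distributions are used
where printed: beta for the response rate (35.52, 39.61), 25-week relapse
(4.03, 26.97; halved to the cycle scale after drawing), AE probabilities,
and the utility *weights* for glaucoma (214.32, 13.68) and cataract before
(62, 38) and after (90, 10) surgery — the weights are applied as
`disutility = 1 - draw`, which reproduces the deterministic 0.061, 0.38 and
0.10 at the distribution means; a normal(0.12, 0.08) for the IVIG utility
increment (so ~2% of draws make IVIG harmful, matching the published
interval). Where the source names a family but prints no spread (gamma AE
costs, normal fracture/diabetes disutility and mortality increments,
baseline utilities), the spread defaults to sd = 20% of the mean
(`rel_sd` in `default_psa_specs()`), applied as a multiplier on age-banded
tables so the age structure is preserved. Unit IVIG and steroid drug costs
stay fixed, which is why the probability that IVIG is cost-effective at
$50,000/QALY is essentially zero in every draw. Draws use one substream per
parameter derived from the master seed, so adding a parameter does not
perturb the others.

Numerical conventions: the CEAC counts strictly positive net monetary
benefit (`lambda x dQALY - dCost > 0`); ties count as not cost-effective;
with every distribution degenerate the PSA reproduces the deterministic
basecase exactly at every threshold (tested).

## Design choices made where the design was open

* **Whole cycles.** Horizons run as `round(h x 52/12)` cycles; fractional
  final cycles are not modelled. The deviation is <2% of any horizon.
* **Relapse window under "no extrapolation".** The 25-week trial window
  covers cycles 1-2, so the stop-after-25-weeks scenario applies relapse at
  the first two transitions only; responder occupancy is constant afterwards
  (absent mortality).
* **Post-AE switch scenario.** The published scenario's incremental cost
  (-$8.4k) and QALYs (-0.011) are only consistent with fracture, diabetes,
  glaucoma and infection patients all restarting IVIG once the AE resolves
  or is discovered, and cataract patients not (their post-surgical state is
  permanent). The engine routes tunnel exits accordingly under the switch
  flag, which applies to the steroid arm only. A literal
  "only-otherwise-off-treatment" reading moves incremental cost by only
  ~-$1.4k and is not compatible with the published row.
* **Mortality ordering.** Background death first, AE increment on
  survivors; the infection case-fatality is an episode probability and is
  not rate-converted.
* **Residual gap.** With these choices the basecase reproduces the published
  incrementals to dC -3.9%, dQ -2.1%, ICUR -1.6% — inside the ±5% band that
  absorbs the unstated cycle-count, half-cycle and life-table choices.
  Annual-step discounting would shrink the cost gap but cancels in the ICUR;
  a half-cycle correction moves the ICUR to -5.6% (away from the published
  value), supporting the no-correction default.

## Known limitations

* The 20-year-horizon scenario computes an ICUR ~6% below the published row:
  the incremental-QALY tail at long horizons is dominated by between-arm
  differences in post-AE residual disutility, a structure the source does
  not print; no defensible switch we tested (life-table slope, half-cycle
  correction, discounting convention) closes it without degrading rows that
  currently match.
* Steroid-arm *totals* ($2,196 / 3.785 QALYs published) are reproduced less
  closely than the incrementals, consistent with the source not ageing the
  background-utility band over the horizon; the incrementals — the decision
  quantities — are insensitive to this.
* No indirect/societal costs, no plasma-exchange comparator, no time-varying
  steroid AE hazards, and microsimulation exists only as a testing oracle.
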