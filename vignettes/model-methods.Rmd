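---
title: "A Markov cohort model of heart-failure telemonitoring under pandemic care avoidance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model of heart-failure telemonitoring under pandemic care avoidance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telecea)
```

## The decision problem

During the COVID-19 pandemic a substantial fraction of older heart-failure
(HF) patients avoided in-person clinic care, losing the benefit of
guideline-recommended multidisciplinary management (MDC) and facing higher
monthly risks of HF-related hospitalization and all-cause death.
Smartphone telemonitoring — daily transmission of heart rate, blood
pressure, weight and symptom reports to the HF team — offers a remote
substitute for the forgone clinic care. `telecea` implements a Markov
cohort decision model that asks whether adding such a program to current
care is good value from a health-care provider's perspective.

Two strategies are compared over a 10-year horizon of monthly cycles:

* **CUC** — care under COVID-19: all patients receive MDC, but a fraction
  (26.1% at base case) avoids in-person care for the duration of the
  pandemic disruption (1.5 years at base case);
* **TM** — the same care plus the telemonitoring program.

Outcomes are discounted direct medical cost (US $, 2020), discounted
quality-adjusted life-years (QALYs), and the incremental
cost-effectiveness ratio (ICER), judged against a willingness-to-pay
(WTP) threshold of US $48,937/QALY (one GDP per capita).

## Model structure

Alive patients occupy one of the four NYHA functional classes; the fifth
state is death. Each monthly cycle, in order:

1. **Events.** Every alive patient faces a monthly probability of
   HF-related hospitalization ($p_h$) and of all-cause death ($p_d$),
   flat across NYHA classes, exactly as the inputs provide them.
2. **Death as a competing event.** A fraction $p_d$ of every alive state
   moves to death. The printed 4×4 NYHA transition matrix is
   row-stochastic among alive states, so it must be conditional on
   survival; survivors are redistributed by it.

The two probabilities are modified multiplicatively per patient stratum:

* *Avoiders*, while avoidance lasts (`ceiling(12 × duration)` = 18
  cycles), face the risks **without** MDC, obtained by dividing the MDC
  probabilities by the MDC risk ratios (hospitalization 0.74, death
  0.75).
* In the TM arm, patients who **avoid in-person care and adhere to the
  program** (adherence 80% at base case, independent of avoidance) have
  both probabilities multiplied by the telemonitoring risk ratios
  (hospitalization 0.50, death 0.81), over the full horizon.

That scope — telemonitoring acting on the avoider-and-adherent stratum —
is a deliberate structural choice. The program is modeled as a remote
replacement for the clinic care that avoiders forgo; non-avoiders keep
attending the clinic and their management is unchanged. We examined the
alternative reading in which the risk ratios apply to every adherent
patient, and it is irreconcilable with the published results this model
reproduces: a 19% mortality reduction applied to 80% of the cohort for
ten years yields an incremental QALY gain several times larger than the
published 0.0662, and an incremental cost several times larger than the
published US $284, while the avoider-scope model reproduces the full
published result set — including both threshold analyses — within the
tolerances below.

### Accrual

With accrual-basis occupancy $o_c$ over classes $c$ and alive mass
$a = \sum_c o_c$, a cycle accrues

$$\text{QALY} = \sum_c o_c\,\bigl(u_c - p_h d_c\bigr)\,\frac{1}{12},
\qquad
\text{cost} = a\,C_{\text{outp}} + a\,(p_h + p_d)\,C_{\text{day}} L +
a\,F_{\text{TM}},$$

where $u_c$ is the annual utility weight of class $c$, $d_c$ the
hospitalization disutility (applied as an expected within-cycle decrement
$p_h d_c$ on the annual weight — the simplest reading; a per-event toll
scaled by length of stay differs materially only in class IV),
$C_{\text{outp}}$ the monthly outpatient cost, $C_{\text{day}} L$ the
admission cost (daily cost × length of stay), and $F_{\text{TM}}$ the
monthly telemonitoring fee. Both accruals are discounted by
$(1+r)^{-t/12}$ with $r = 0.03$ per year and $t$ the 0-based cycle.

Two cost conventions deserve emphasis:

* **Terminal admission.** Each death incurs one HF admission cost — the
  $p_d$ term above — reflecting that decompensation deaths in this
  population occur in hospital. Without it the model's cost level is
  about 28% below the published totals; with it the 1.5-year cost
  comparison matches to a fraction of a percent, so it is treated as part
  of the model structure.
* **Telemonitoring costs.** The one-time setup cost (US $80) is charged
  for every TM-arm patient at entry, undiscounted. The recurrent fee
  (US $50/month) accrues for the avoiders the remote service manages,
  adherent or not (equipment and licensing are sunk once issued). This
  cost scope is pinned by the published fee threshold: the largest
  monthly fee keeping the ICER below WTP (US $467) implies the fee's
  marginal cost mass is roughly seven discounted member-months, which is
  the avoider stratum, not the whole arm.

**Half-cycle correction** is on by default: accrual uses the average of
start- and end-of-cycle occupancy, approximating mid-cycle transitions.
`analysis_config()` exposes `half_cycle_correction` and
`accrual_timing` (`start_of_cycle`/`end_of_cycle`); with the correction
off and start-of-cycle accrual the totals rise by about 1.5%.

## Parameters

`default_parameters()` returns the base case; `parameter_specs()` the
per-input sensitivity ranges and distribution families
(`write_parameter_csv()` dumps them). Key values: initial NYHA
distribution (9/44/34/13%), monthly NYHA transition matrix, monthly MDC
event probabilities (hospitalization 0.0296, death 0.0279), the four
risk ratios above, utilities 0.82/0.74/0.64/0.46 and hospitalization
disutilities 0.04/0.07/0.10/0.29 by class, admission US $654/day × 8
days, outpatient US $197/month, telemonitoring US $80 + US $50/month.
The NYHA-IV transition row is published with the NYHA-III row's ranges
(an apparent typesetting slip); its base values sum to one and are kept,
and its perturbation ranges are regenerated as ±20% of base, capped to
the unit interval. Inputs without a published range default to ±20% of
base (`dsa_default_range_fraction`).

`load_parameters()` reads a JSON document overriding any field (unknown
keys rejected, invariants re-validated); `serialize_parameters()` writes
one back, round-tripping field-for-field.

## Deterministic sensitivity analysis

`one_way_dsa()` re-runs both arms at each elementary input's range ends.
The tornado metric is the signed incremental cost per QALY: where an
endpoint falls in the dominant quadrant the ratio is negative and the
dominance label is recorded alongside, so dominant endpoints widen a
parameter's spread rather than vanish from the ranking (the ICER alone
is undefined across quadrants). Perturbing one simplex component
(initial distribution or a transition-matrix cell) rescales the
remaining components proportionally over the remaining mass, preserving
row-stochasticity; values pushed past their domain are clamped with a
warning. Inputs whose ICER moves by more than 20% are flagged critical —
at base case exactly eight inputs are flagged, and no input's range
produces an ICER above the WTP threshold.

`threshold_search()` performs bisection (relative tolerance $10^{-4}$)
on either the incremental cost (onset of dominance) or the ICER−WTP gap,
after verifying a sign change at the bracket ends; `two_way_dsa()` maps
the (hospitalization, mortality) telemonitoring risk-ratio plane
(default 51×51) and labels each cell by the WTP decision rule.

## Probabilistic sensitivity analysis

The published inputs give a distribution *family* per parameter but no
hyperparameters, so `build_assignments()` derives them from
`(base, low, high)` under declared conventions:

* **beta** — mean at base; concentration solved numerically so the
  central 95% interval has width `high − low` (uniform fallback if
  infeasible);
* **gamma** — mean at base, sd `(high − low)/3.92`;
* **lognormal** (risk ratios) — median at base, `sdlog`
  `(log high − log low)/3.92`;
* **triangular** — `(min, mode, max) = (low, base, high)`;
* **uniform** — `(low, high)`; zero-width ranges are point masses;
* **Dirichlet** (initial distribution and each transition row) —
  concentration `κ × base`, with `κ` set so the largest component's sd
  matches its range width `/3.92`; structural zeros stay zero.

All parameters are drawn independently (no correlation information is
published); rows are drawn independently per row. `run_psa()` uses a
single seeded RNG stream, drawing each iteration's full parameter set
and running both arms; iteration order is deterministic for a fixed
seed. Sampled probabilities are clamped into `[0, 1]` and the clamp rate
reported. `ceac()` computes, per WTP grid point, the fraction of
iterations with positive incremental net monetary benefit (ties count
for CUC); `ceac_crossover()` interpolates the 50% crossing.

Because the hyperparameterization is a convention, PSA summaries are
expected to match the published values only loosely (means within
roughly 10%, acceptability within a point); the deterministic results do
not depend on it.

## Validation against a microsimulation oracle

`microsimulate()` samples individual patient trajectories under exactly
the cohort dynamics — stratum attributes at entry, initial class from
the initial distribution, then per cycle sampled hospitalization, death
and NYHA movement with the same probabilities — and accrues realized
costs and QALYs. Its sample mean is an unbiased estimator of the cohort
totals under start-of-cycle accrual, so equivalence checks run with the
half-cycle correction off (event-based costs cannot be averaged over
half-cycles without changing their expectation).
`random_parameter_set()` generates structurally valid random models
(Dirichlet rows with diagonal dominance, utilities decreasing in class).
The test suite checks agreement within three standard errors at 50,000
patients across 100 random parameter sets over a 3-year horizon, plus a
sign test for centredness across seeds; these sizes keep the suite's
runtime modest while leaving the Monte Carlo error far below any effect
of interest.

## What the tests do and do not show

The synthetic validation exercises the identical dynamics the cohort
engine defines; agreement demonstrates the deterministic engine and the
stochastic implementation are two faithful computations of the same
expectations. It does not validate the model against real patients: NYHA
transitions are first-order Markov with class-independent event risks,
avoidance and adherence are time-fixed independent attributes, there is
no age-dependent background mortality, no COVID-19 infection states, no
treatment switching or re-adherence, and costs are a stylized three-item
basket. Those are modeling assumptions inherited with the published
inputs, not conclusions.

## Reproduced results

With the defaults, `run_report()` reproduces the published analysis
within the stated bands (deterministic ±15%, probabilistic ±20%): CUC
US $15,643 / 1.8410 QALYs against published 15,603 / 1.8345; TM
US $15,931 / 1.9164 against 15,888 / 1.9007; incremental US $288 /
0.0755 QALYs (published 284 / 0.0662); ICER US $3,821/QALY (published
4,292); avoidance impact over 1.5 years +US $211 / −0.0161 QALYs
(published +226 / −0.0175); dominance threshold for the hospitalization
probability 0.0497 (published 0.0515); fee threshold US $450/month
(published 467). The residual gaps, largest in the incremental QALY,
are attributable to unrecoverable details of the original
implementation; every convention we can vary (accrual timing, half-cycle
handling, disutility treatment) moves the base case by far less than
these bands.

## Numerical choices

Equivalence tolerances in comparisons are $10^{-12}$ QALY and $10^{-9}$
dollars, far below any input's resolution. Mass conservation is enforced
to $10^{-9}$ per cycle. Bisection uses relative tolerance $10^{-4}$ with
explicit endpoint-sign verification. A zero-cycle horizon accrues
nothing except the telemonitoring setup cost. Effective probabilities
exceeding one after the avoidance division are clamped with a warning.
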