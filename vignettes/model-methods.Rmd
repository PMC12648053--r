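---
title: "A Markov cost-utility model for protein-restricted diets in advanced CKD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cost-utility model for protein-restricted diets in advanced CKD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ckdcea)
```

## The decision problem

Patients with chronic kidney disease (CKD) stages 4–5 (eGFR < 30 mL/min/1.73 m²)
face progression to end-stage renal disease and kidney replacement therapy,
overwhelmingly dialysis. Dietary protein restriction slows that progression. A
very-low-protein diet (0.3–0.4 g/kg/day) supplemented with ketoanalogues —
nitrogen-free amino-acid analogues transaminated to essential amino acids
in vivo — delays dialysis initiation markedly compared with a conventional
low-protein diet (0.6 g/kg/day), at the price of a daily supplement cost and
more intensive dietary monitoring. `ckdcea` implements the lifetime
cost-utility comparison of the two regimens (s-VLPD vs LPD) for the Italian
setting, from a healthcare-payer (NHS) or a societal perspective.

## Model structure

The model is a discrete-time Markov cohort simulation with three health
states: **pre-dialysis**, **dialysis** and **dead**. The whole cohort starts
in pre-dialysis; at each monthly cycle a patient can stay, start dialysis or
die. Dialysis is absorbing except for death, and death is absorbing. Both
strategies share the structure; only transition probabilities and cost
profiles differ.

### From annual probabilities to monthly transitions

The published clinical inputs are annual probabilities: 24.4 %/yr dialysis
onset under LPD, 11.1 %/yr pre-dialysis mortality, 13.8 %/yr dialysis
mortality, and an adjusted hazard ratio of 0.237 (95 % CI 0.22–0.26) on
dialysis onset for s-VLPD. Each annual probability $p$ is converted to a
constant hazard $r = -\ln(1 - p)$; the hazard ratio is applied on the hazard
scale, $p' = 1 - (1-p)^{\mathrm{HR}}$, which is identical to multiplying the
rate.

Within a cycle, dialysis onset and pre-dialysis death compete. The package
sums the annual hazards, converts the sum to a single per-cycle exit
probability $1 - e^{-(r_d + r_m)\,h}$ (cycle length $h = 1/12$ y), and
allocates exits to destinations proportionally to their hazards — the exact
result for competing exponential risks. At monthly cycles this is numerically
indistinguishable (5 significant figures) from multiplying independent
per-cycle probabilities, but the rate formulation is the documented contract
and is what the closed-form oracle below validates.

### Half-cycle correction and stopping rule

Transitions in reality occur throughout a cycle, not at its boundary. State
time is therefore credited as the average of start- and end-of-cycle
occupancy (trapezoid rule); the `half_cycle_correction` flag exposes the
uncorrected end-of-cycle convention for comparison. The simulation stops when
the alive fraction falls below $10^{-4}$ (about 63–80 years of simulated time
under base-case hazards) or at a hard cap of 1440 cycles; with everything at
default the truncated tail contributes under $10^{-3}$ years.

Hazards are constant: the published inputs are flat annual probabilities and
no age-dependent background mortality is layered on top. Age advances with
model time only for the work-value lookup of the societal perspective.

### Validation against a closed form

For constant hazards the continuous-time expectations are available in closed
form: mean pre-dialysis time $1/(r_d + r_m)$, probability of ever reaching
dialysis $r_d/(r_d + r_m)$, and mean dialysis time
$[r_d/(r_d+r_m)]\,/\,r_{m,\mathrm{dial}}$. The test suite checks the trace
against these oracles within one cycle length (1/12 y) across 100 randomized
parameter sets, and the base case lands on the published state times
(LPD 2.54/4.74 y, s-VLPD 5.44/2.43 y) within ±0.05 y:

```{r basecase}
run <- run_base_case(default_parameters())
base_case_table(run)[1:4, ]
```

## Outcomes and discounting

Costs and QALYs are discounted at 3 %/yr, applied per cycle as
$(1.03)^{-m/12}$ at the start of each monthly interval. Survival and state
times are reported **undiscounted**: the published survival figures are only
consistent with undiscounted time, despite a blanket statement that outcomes
are discounted; the `discount_life_years` flag applies the literal reading
for users who want it. QALYs weight pre-dialysis time by a single utility and
dialysis time by the modality-mix-weighted mean of haemodialysis (HD), CAPD
and APD utilities (83.8 %/7.7 %/8.5 % from census frequencies).

### Cost accrual rules

| item | accrues | rule |
|---|---|---|
| ketoanalogues | pre-dialysis, s-VLPD only | 18 tablets/day (6 three times daily) × unit price |
| diet monitoring | pre-dialysis | 1 visit/month (s-VLPD), 1 visit/2 months (LPD) |
| dialysis | dialysis | mix-weighted monthly tariff + PD annual maintenance amortized monthly |
| PD catheter | dialysis entry | one-off × PD share, discounted at the entry cycle |
| other supplements | pre-dialysis | usage × dose × price, by diet profile |
| indirect | dialysis, societal only | productivity loss + informal care (below) |

Per-day resources convert at 365.25/12 days per month. The ketoanalogue dose
uses the average adult posology for costing rather than the weight-based
trial rule (1 tablet per 5 kg), matching the costing convention of the
reference analysis.

The indirect cost per patient-month in dialysis is
$\sum_m s_m \, \ell_m \, W(\text{patient})$ — modality shares $s_m$, fraction
of the week lost $\ell_m$ (0.50 HD, 0.30 CAPD, 0.20 APD), and the monthly
value of paid and unpaid work $W$ stratified by gender and age band — plus a
caregiver term: 24.5 % of dialysis patients need informal care for 12 h/week
(HD) or 2 h/week (PD); weekly hours are scaled by a 40-hour reference week (a
package convention — the sources give hours per week and a monthly work
value but no conversion rule) and valued at the caregiver work value
(58 % male, age 51.7). The patient work value is cohort-weighted (55.8 % male
aged 70, 44.2 % female aged 72) and re-looked-up each cycle as the cohort
ages. The work-value table is interpreted as already averaged over employment
status; the caregiver employment share is carried as an input for users who
substitute employment-stratified values.

## Placeholder inputs

Unit prices (ketoanalogues ≈ €0.40/tablet, monitoring ≈ €20/visit), dialysis
tariffs (HD ≈ €1600, PD ≈ €1200 per month), PD one-off costs, utilities
(pre-dialysis ≈ 0.80, dialysis ≈ 0.58–0.64) and the work-value table ship as
**placeholders** tagged `supplementary_placeholder`: the reference analysis
publishes these only in a supplementary file. They are order-of-magnitude
plausible for the Italian setting so that every cost and QALY code path is
exercised and the qualitative conclusion (dominance of s-VLPD) is
reproduced, but absolute cost and QALY magnitudes are **not** comparable to
the published totals until a user transcribes the supplementary values into
the configuration (`load_parameters()` / `set_parameter()`). The state-time
results above depend only on in-text inputs and are unaffected. A related
wrinkle documented here for transparency: the published base-case table
reports slightly different "other supplementation" totals under the payer and
societal perspectives with no stated mechanism; this package keeps supplement
costs perspective-invariant.

## Sensitivity analyses

**Deterministic (one-way):** cost parameters and the dialysis-modality mix
move ±20 % (a perturbed share is renormalized against the other two,
preserved in proportion); clinical-efficacy and utility parameters move
across their 95 % CIs. A parameter whose interval collapses to the point
estimate is skipped — the package deliberately refuses to invent ranges.
Only the hazard ratio's CI is published in-text; the onset and mortality
probabilities carry placeholder ±10 % ranges so the mortality axis of the
tornado is populated. Tornado ordering uses the incremental-cost swing.

**Probabilistic:** 1000 parameter draws per run. Families are chosen by
parameter class — beta for probabilities and utilities (moment-matched to
the point estimate and its interval, sd = width/3.92), log-normal for the
hazard ratio, gamma for costs, Dirichlet for the modality mix with
concentration matched to the HD share's interval. Tying every spread to the
deterministic interval gives a clean degeneracy property: collapse all
intervals and every draw reproduces the base case exactly, which the tests
assert. Draws are reproducible from a seed and the caller's RNG state is
restored. Outputs: the cost-effectiveness plane, a normal-theory 95 %
confidence ellipse (mean + covariance scaled by the $\chi^2_2$ quantile),
and the acceptability curve (fraction of draws with positive net monetary
benefit per willingness-to-pay). Under the default spreads the curve stays
at essentially 1 across €0–100 000/QALY, matching the qualitative published
finding.

```{r psa, fig.width = 6, fig.height = 4}
psa <- run_psa(default_parameters(), n = 200, seed = 1)
plot_ce_plane(psa)
```

(The figure above uses 200 draws to keep the vignette light; analyses use
1000.)

## Scenario analyses

* **Societal perspective** — same traces, indirect items added.
* **Dialysis-mortality benefit** — evidence from ketoanalogue-exposed
  dialysis starters (all-cause mortality HR 0.77) motivates reducing the
  s-VLPD arm's dialysis mortality to 10.8 %/yr; the LPD arm is untouched.
  Time in dialysis for s-VLPD rises from ≈2.4 to ≈3.2 years and the survival
  gain to ≈1.3 years, matching the published 3.13/1.30 within ±0.1 y.
* **Partial adherence** — 42 % of the s-VLPD cohort switches to LPD linearly
  over the first 6 months. The arm's state space expands to
  {pre-s-VLPD, pre-switched, dialysis, dead}: an equal flow of 42 %/6 of the
  *initial* cohort moves per cycle (capped at current occupancy; a
  `proportional` mode implements the alternative constant-switching-hazard
  reading). Switchers keep the 11.1 %/yr pre-dialysis mortality, adopt the
  LPD dialysis-onset hazard and the LPD cost profile (no ketoanalogues,
  bimonthly monitoring, LPD supplement usage) from the switch onward. Under
  this literal reading the survival gain attenuates to ≈0.35 y — positive
  and well below the full-adherence 0.60 y, but larger than the ≈0.25 y the
  reference analysis reports; its exact switching mechanics (whether the
  42 % applies to survivors, and what else changes on switching) are not
  recoverable from the text, so the package treats the printed value as a
  plausibility band rather than a reproduction target. Scenario neutrality
  is tested: each scenario with its distinguishing parameter at the base
  value reproduces the base case.

Combined scenarios (e.g. adherence plus mortality benefit) are not part of
the reference analysis and are not composed by default.

## Numerical conventions and limitations

* Problem sizes: lifetime traces run 700–1000 monthly cycles; the oracle
  property uses 100 randomized sets at ±30 % jitter; PSA robustness uses
  5 seeds × 1000 draws. All are full-scale — nothing is scaled down.
* Ties/degenerate inputs: all-zero exit hazards leave the cohort parked and
  flag the trace unconverged; a zero-width sensitivity interval produces a
  zero-width tornado bar; a singular PSA covariance flags the ellipse
  degenerate rather than inverting it.
* The model has no transplantation state, no hospitalization or
  complication costs, and no age-dependent hazard drift — consistent with
  the reference structure, which lists these as unquantified limitations.
* The randomized-set generator perturbs substantive inputs only; model
  settings (cycle length, horizon, discounting flags) stay fixed. It
  emulates parameter-level uncertainty, not patient-level heterogeneity, so
  passing property tests demonstrates internal consistency of the cohort
  machinery, not fidelity to any real cohort.
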