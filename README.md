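# ckdcea

Cost-utility modelling of ketoanalogue-supplemented very-low-protein diets in
advanced chronic kidney disease.

## The problem

In CKD stages 4–5 (eGFR < 30 mL/min/1.73 m²), dietary protein restriction
slows progression to dialysis. A very-low-protein diet (0.3–0.4 g/kg/day)
supplemented with ketoanalogues of essential amino acids (s-VLPD) delays
dialysis initiation substantially compared with a conventional low-protein
diet (LPD, 0.6 g/kg/day) — at the price of a daily supplement cost and more
frequent dietary monitoring. Whether the delay pays for itself is an
economic question: a month in pre-dialysis care costs a small fraction of a
month on dialysis.

`ckdcea` answers it with a discrete-time Markov cohort model: three states
(pre-dialysis → dialysis → dead), monthly cycles, lifetime horizon,
half-cycle correction, 3 %/yr discounting of costs and QALYs, from a
healthcare-payer or societal perspective. Clinical inputs are annual
probabilities converted to constant hazards, with the s-VLPD effect applied
as a hazard ratio (0.237) on dialysis onset; competing risks within a cycle
are resolved exactly for exponential hazards. The package includes one-way
deterministic sensitivity analysis (tornado), probabilistic sensitivity
analysis (cost-effectiveness plane, 95 % confidence ellipse, acceptability
curve) and three scenario analyses (societal perspective,
dialysis-mortality benefit, partial adherence with treatment switching).
Methods, conventions and limitations are documented in the vignette
(`vignettes/model-methods.Rmd`).

**Caveat on cost magnitudes:** unit prices, dialysis tariffs, utilities and
work values ship as clearly tagged placeholder values (provenance
`supplementary_placeholder`) of plausible magnitude for the Italian setting.
State-time and survival results depend only on published clinical inputs
and are exact reproductions; absolute euro and QALY totals are illustrative
until you supply your own unit costs via the YAML configuration.

## Worked example

```r
library(ckdcea)

params <- default_parameters()   # or load_parameters("my_config.yaml")
run <- run_base_case(params, perspective = "nhs")
print(run)
```

```
<ckdcea_run> LPD vs s-VLPD, nhs perspective
                 outcome          lpd        svlpd         delta
          survival_years     7.285618     7.877539  5.919202e-01
 time_pre_dialysis_years     2.516764     5.436330  2.919566e+00
     time_dialysis_years     4.768854     2.441208 -2.327646e+00
                   qalys     4.056569     4.784805  7.282356e-01
       cost_ketoanalogue     0.000000 12332.412267  1.233241e+04
         cost_monitoring   281.446153  1125.476821  8.440307e+02
           cost_dialysis 68747.679424 32579.197009 -3.616848e+04
  cost_other_supplements   445.263093   656.896706  2.116336e+02
              total_cost 69474.388670 46693.982803 -2.278041e+04
verdict: dominant
```

Reading the table: s-VLPD almost triples time spent pre-dialysis (5.44 vs
2.52 years), cuts time on dialysis (2.44 vs 4.77 years), and extends
survival by 0.59 years. The supplement and monitoring costs
(about €13 200 more per patient) are swamped by €36 200 of avoided
dialysis cost, so s-VLPD is *dominant* — more effective and cheaper — and
no incremental cost-effectiveness ratio is defined.

Sensitivity and scenario analyses:

```r
dsa <- run_dsa(params)                      # one-way tornado table
plot_tornado(dsa, "cost")

psa <- run_psa(params, n = 1000, seed = 42) # probabilistic
plot_ce_plane(psa)                          # with 95% confidence ellipse
plot_ceac(ceac(psa))                        # acceptability curve

run_societal(params)                        # adds productivity + caregiver costs
run_mortality_benefit_scenario(params)      # s-VLPD dialysis mortality 10.8%/yr
run_adherence_scenario(params)              # 42% switch to LPD over 6 months
```

Every substantive input carries a provenance tag, an optional uncertainty
interval, and can be overridden:

```r
p <- set_parameter(params, c("unit_costs", "tariff_hd_monthly"), 1750)
serialize_parameters(p, "my_config.yaml")   # round-trip-stable YAML
```

A command-line wrapper ships at `inst/cli/ckdcea.R`
(`Rscript ckdcea.R {run|dsa|psa|scenario|fixtures} [options]`), and the
default configuration at `inst/extdata/default_params.yaml`.

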