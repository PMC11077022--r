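# copdsim

Individual-level microsimulation of chronic obstructive pulmonary
disease (COPD) natural history and clinical management in the Chinese
adult population, with a full cost-effectiveness layer for evaluating
population-based screening policies.

COPD is heavily underdiagnosed in China — fewer than 3% of patients are
aware of their condition — so most patients miss the window for early
treatment. The policy question this package addresses: is it worth
screening the *general* adult population (not just high-risk groups),
with what instrument, and how often?

## The model

A closed cohort of one million simulated adults aged 35–80 (any size
runs; results scale per person) is followed in 3-month cycles over a
lifetime horizon. Each person carries lung function (FEV1, liters),
FEV1 percent-of-predicted, GOLD stage (1–4 from the ≥80 / 50–79 /
30–49 / <30 percent-predicted bands), diagnosis and treatment status.
Per cycle:

- **FEV1 decline**: annual loss ~ N(μ_stage, σ), μ = 40/60/56/34 ml/yr,
  multiplied by 1.957 for 12 months after an exacerbation, reduced by
  treatment (73–201 ml/yr for the 12-month treatment course).
- **Exacerbations**: Poisson, stage-specific annual rates
  (non-severe 0.71–1.82, severe 0.11–0.28), scaled by treatment.
- **Mortality**: life-table hazard × stage hazard ratio
  (1.2/1.6/2.7/2.7) × treatment relative risk; COPD-attributed deaths
  by the excess-hazard fraction (HR·rr − 1)/(HR·rr).
- **Care cascade**: symptom-driven diagnosis at small per-cycle,
  stage-specific probabilities calibrated to observed awareness by
  stage; screening (one-step COPD-SQ questionnaire, sens/spec
  0.57/0.82, or two-step adding a portable spirometer, 0.85/0.85) with
  40% follow-up confirmatory spirometry and 30% treatment uptake.
- **Economics**: age-band baseline utilities adjusted by GOLD stage
  (0.806/0.767/0.704/0.616), per-event exacerbation disutilities;
  payer-perspective 2022 USD costs (maintenance, treatment,
  exacerbation, screening, diagnosis); 3%/yr midpoint discounting.

Eleven policies are compared under exact common random numbers: status
quo, and {one-step, two-step} × {once, every 1/2/5/10 years}. The
decision layer computes ICERs, the dominance frontier (strict +
extended), events averted, linkage-to-care scenario grids, one-way
sweeps, and probabilistic sensitivity analysis with CEACs against a
willingness-to-pay of $38,441/QALY (3× GDP per capita).

## Worked example

```r
library(copdsim)
params <- default_parameters()              # full Table-style registry
cohort <- generate_cohort(20000, params, seed = 1)
#> <copd_cohort> n = 20000, 51.3% male, 12.36% COPD, seed 1

res <- run_policy_set(cohort,
                      list("none", "two_step:10y", "two_step:1y", "one_step:1y"),
                      params, seed = 1)
tab <- cea_table(res)
tab[, c("policy", "qaly", "cost", "icer_vs_statusquo", "frontier_member")]
#>         policy   qaly     cost icer_vs_statusquo frontier_member
#> 1         none 301551 41622981                NA            TRUE
#> 2 two_step:10y 301620 42085527              6682           FALSE
#> 3  two_step:1y 301776 43070801              6442            TRUE
#> 4  one_step:1y 301794 43425287              7420            TRUE

res[["none"]]$total_qaly_discounted / 20000
#> 15.078                       # discounted QALYs per person, status quo
most_cost_effective(tab, params$wtp)
#> "one_step:1y"                # best frontier policy within the WTP
```

Reading the output: each row is one policy's lifetime discounted QALYs
and costs for the 20,000-person cohort; `icer_vs_statusquo` is dollars
per QALY gained over no screening (all far below the $38,441 WTP, so
every screening policy is cost-effective here); `frontier_member`
marks policies not removed by strict or extended dominance. At this
small n the ICERs are noisy — the reproduction runs below use 100,000
persons × 3 seeds.

Other entry points: `calibrate_symptom_diagnosis()` (awareness
calibration), `linkage_scenario_grid()`, `one_way_sweep()`,
`run_psa()` + `ceac()`, and the command wrappers `cmd_simulate()`,
`cmd_table2()`, `cmd_calibrate()` (see also `inst/cli/copdsim.R`).

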