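---
title: "copdsim: model, assumptions and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{copdsim: model, assumptions and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`copdsim` is an individual-level microsimulation of chronic obstructive
pulmonary disease (COPD) in the Chinese adult population, built to
compare population-based screening policies against the status quo of
symptom-driven diagnosis.  This vignette documents the model structure,
the parameter conventions, the numerical choices, and the places where
the design was genuinely open and the package had to commit to one
reading.

## The cohort and the disease process

A closed cohort of adults aged 35-80 is generated with the age-band and
sex structure of China's adult population (band weights from the 2020
census, 51.1% male; uniform ages within bands).  COPD prevalence at
baseline is assigned by sex and age band; prevalent cases draw FEV1
percent-of-predicted from sex-specific normals (male mean 0.797, female
0.835, sd 0.206), truncated to [0.05, 1.30].  GOLD stage follows the
standard bands on percent-predicted: >= 80% stage 1, 50-79% stage 2,
30-49% stage 3, < 30% stage 4.

Time advances in 3-month cycles until everyone has died (age 110 is an
absorbing cap).  Each cycle applies, in order: screening (on screening
cycles), symptom-based diagnosis, treatment (re)assignment, incidence,
exacerbations, FEV1 decline and restaging, death, and discounted
QALY/cost accrual.  The within-cycle order is a modelling convention
(the underlying description does not fix one); placing exacerbations
before decline and accrual lets an event affect the same cycle's
lung-function loss, utility and cost.

### Lung function

FEV1 is tracked in liters.  A person's percent-predicted is their FEV1
divided by a sex- and age-specific reference value, here a configurable
linear-in-age fixture (male 4.0 L at 35, -25 ml/yr; female 2.9 L at 35,
-20 ml/yr).  Because the healthy reference itself falls with age, a
COPD patient declining at, say, 40 ml/yr loses percent-predicted (and
hence advances in GOLD stage) much more slowly than if the full decline
were taken out of percent-predicted directly.  This accounting matters:
taking the decline out of percent-predicted against a frozen reference
roughly doubles stage progression and triples COPD-attributed deaths.
A ratchet keeps percent-predicted non-increasing (the reference falls
faster than the FEV1 of a well-treated slow decliner, which would
otherwise let percent-predicted drift up), so stage is monotone
non-decreasing, matching the model's no-recovery assumption.

Annual decline is drawn per cycle from stage-specific normals (means
40/60/56/34 ml/yr, sd 5), floored at zero (decline is a loss process),
multiplied by 1.957 if an exacerbation occurred within the past 12
months (the effect window resets with each new event and does not
stack), minus the treatment reduction, floored at zero again, and
scaled by the cycle length.

### Exacerbations and mortality

Non-severe and severe exacerbation counts are independent Poisson draws
with stage-specific annual rates (0.71/1.01/1.39/1.82 and
0.11/0.16/0.22/0.28) times the treatment relative risk times the cycle
length.  Mortality uses an abridged life table (see below) converted to
a hazard, multiplied for COPD patients by a stage-specific hazard ratio
(1.2/1.6/2.7/2.7) and the treatment relative risk.  A death of a COPD
patient is labelled COPD-attributed with the excess-hazard fraction
`(HR*rr - 1)/(HR*rr)` (clamped at zero); the alternative — counting all
deaths among COPD patients — is not used anywhere.

### Incidence

Persons without COPD convert with per-cycle probability
`1 - exp(-rate * 0.25)` from sex- and age-band incidence rates.  The
oldest-band rate is an estimate for ages 70-85, so the model applies it
through age 85 and generates no new COPD beyond that age
(`incidence_max_age`); extrapolating a ~5%/yr incidence to age 110
would inflate the incident population by roughly a quarter with no
empirical support.  Incident cases draw percent-predicted from the
incident distributions and accrue outcomes at their new state from the
following cycle.  The printed male incident sd (0.906) would put most
draws outside the physiologic range; the package defaults to 0.0906 and
treats the printed value as a typo (the female value, 0.107, is of this
magnitude).

## The care cascade

Under the status quo, undiagnosed COPD patients are found only through
symptom-driven presentation, modelled as a small per-cycle,
stage-specific probability.  These probabilities are calibrated so
that, simulating the status quo with the cohort initialised at the
observed awareness profile (0.63%/2.00%/12.87%/21.04% by stage), the
cross-sectional awareness among living COPD patients stays stationary
at that profile.  The calibrator is a joint proportional fixed-point
iteration on the excess of awareness over the zero-diagnosis floor, one
full simulation per iteration, deterministic given the seed; the
packaged defaults (0.000128, 0.000434, 0.009512, 0.001068 per cycle)
were produced at 200,000 persons, 40 cycles, seed 20.  The calibrated
stage-4 probability is *smaller* than stage 3's: most aware stage-4
patients arrive already diagnosed from stage 3, so stationarity at
21.04% needs little additional diagnosis pressure.  Monotonicity in
stage therefore holds for stages 1-3 but not by construction at stage 4.

Screening excludes the already diagnosed.  One-step screening applies
the COPD screening questionnaire (sensitivity 0.57, specificity 0.82);
two-step screening adds a portable spirometer (0.85/0.85) for
questionnaire-positives.  Screen-positives take confirmatory diagnostic
spirometry with probability 0.40; confirmation is treated as a perfect
gold standard, so false positives pay for the test and return to the
pool with no memory (no repeat-screen exclusion).  The $4 program setup
charge is one-time per person: a per-round charge under annual
screening alone would exceed the documented sub-2% share of screening
in total cost.

### Treatment

Diagnosed patients take up treatment with probability 0.30; those who
do draw one of five archetypes from a stage-specific mix.  The five
defaults are evenly spaced across the published effect ranges
(decline reduction 73-201 ml/yr paired rank-wise with exacerbation
relative risk 0.92-0.62, mortality relative risk 0.99-0.71, and monthly
cost $20.21-104.58), with mix mass shifting toward stronger archetypes
at higher stages.  The archetype identities and mixes are published
only as ranges; all are configurable.

Treatment is modelled as a **12-month course**: the decline reduction,
both relative risks, and the monthly cost all run for
`treat_effect_months` (12), after which the patient reverts to
untreated until a GOLD-stage change triggers a readjustment — a fresh
uptake draw if the course has lapsed, an archetype switch (resetting
the clock) if it is still running.  The course reading was adopted
after testing the alternative (lifetime therapy with only the decline
benefit expiring): lifetime therapy produces an incremental cost of
annual two-step screening of roughly $900 per person and three times
the documented deaths averted, both irreconcilable with the published
incremental outcomes, while 12-month courses land all three incremental
quantities near them.

## Economics

Utilities: the general population carries age-band baselines (0.962,
0.955, 0.944, 0.925, 0.895, 0.855 for 35-39 through 80+ — values at
the scale of Chinese EQ-5D population norms).  COPD patients use the
stage utilities 0.806/0.767/0.704/0.616, applied by default as
multipliers on the age-band baseline normalised at the 60-69 reference
band (so the printed absolute values are reproduced exactly there); an
absolute mode is available by flag.  Exacerbations subtract 0.010
(non-severe) and 0.040 (severe) from the utility weight in the event's
cycle; these per-event decrements are not published at full precision,
and the defaults sit at the scale typical of COPD cost-effectiveness
studies.

Costs (2022 USD, payer perspective): questionnaire $0.72, spirometer
$2.90, setup $4.00 one-time, diagnostic spirometry $26.93; monthly
maintenance by stage $7.66/$24.25/$34.56/$54.04; exacerbation events
$68.24/$2987.06; treatment monthly cost per archetype.  Maintenance
accrues for **every** COPD patient, diagnosed or not: conditioning it
on diagnosis makes a screening program add ~$395/person of maintenance
spending by itself, several times the documented total incremental cost
of the most intensive policy, so the published accounting cannot have
been diagnosis-conditional.  A per-cycle complication (e.g. pneumonia)
cost hook exists per stage and defaults to zero; the complication
costing behind the published totals is not specified in enough detail
to reproduce, which is the main reason the package's status-quo total
cost runs above the headline figure while incremental costs between
policies match well.

QALYs and costs accrue per cycle, discounted at 3%/yr at the cycle
midpoint with factor `(1+r)^(-t)`; persons dying within a cycle accrue
half a cycle of utility and of the monthly-rated cost categories, while
per-event costs charge in full.  Cost categories
(screening/diagnosis/maintenance/treatment/exacerbation/complication)
sum exactly to the total.

## Decision layer

ICERs compare policies as cost difference over QALY difference, with
dominance verdicts instead of divisions where the sign structure calls
for them.  The frontier starts at the cheapest policy and repeatedly
steps to the minimum-ICER policy among those with more QALYs; this
implements strict plus extended dominance and is tested against a
brute-force blend-domination oracle.  "Most cost-effective at a
willingness-to-pay" is the frontier policy with the largest QALYs whose
incremental frontier ICER is within the threshold ($38,441/QALY, three
times GDP per capita, by default).  The linkage-to-care grid re-runs
the policy set over follow-up-diagnosis and treatment-uptake
probabilities; one-way sweeps re-run it at a parameter's low/high
values; the PSA draws parameters (beta for probabilities and utilities,
gamma for costs and rates, normal for effect sizes; 95% intervals of
roughly +/-20% of the mean, a documented package default) and records per-policy QALY/cost pairs for
cost-effectiveness acceptability curves with net-monetary-benefit
winners and equal tie-splitting.

## Random numbers and reproducibility

Every stochastic process draws from a named uniform stream seeded by a
32-bit hash of (master seed, process id, cycle index), drawn
full-cohort-length in person order.  Two policies run from the same
master seed therefore consume *identical* uniforms for every (person,
process, cycle) triple — exact common random numbers — so paired
differences between policies are attributable to the policy.  An
independent mode derives a distinct master seed per policy.  No
function disturbs the caller's RNG state.

## Fixtures and what the synthetic data do not show

The life table is a synthetic abridged fixture
(`inst/extdata/life_table_synthetic.csv`, ages 35-100 by sex) built by
log-linear interpolation between Gompertz-like anchors chosen so that
remaining life expectancy at 35 is 42 years for men and 46.6 for women,
matching published Chinese values; beyond 100 the hazard grows 15%/yr
and is absorbed at 110.  The FEV1 reference equations and the census
band weights are similarly package-level fixtures.  Simulated cohorts
emulate the *marginal* structure the analysis assumes — prevalence,
incidence, FEV1 distributions, awareness by stage — but not joint
features of real populations (smoking, comorbidity, clustering of risk
within households or regions), so passing tests demonstrate internal
consistency of the model chain, not external validity.

## Problem sizes and known limitations

The package's reproduction runs use 100,000 persons with three seeds
and common random numbers, scaling person-level means to the
one-million cohort; Monte Carlo error on per-person QALYs at this size
is well under 0.1%.  Calibration uses 200,000 persons over 40 cycles.

Known limitations, beyond those inherited from the model design (no
smoking dynamics, no treatment non-adherence, stage-level rather than
symptom-level treatment): the complication-cost hook defaults to zero,
so total (but not incremental) costs are understated relative to a
full costing; the excess-hazard death attribution combined with the
printed prevalence/incidence yields substantially more COPD-attributed
deaths than the headline figure, and back-computation from the
published outcome set suggests the original incidence handling or
death definition differs in unpublished detail; and the life table and
utility baselines are package fixtures, to which total QALY levels are
directly sensitive.
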