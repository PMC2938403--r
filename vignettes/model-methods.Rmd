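---
title: "Model structure and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dppcea)
```

## The decision problem

`dppcea` models a screening-plus-intervention policy for adults at elevated
risk of type 2 diabetes and cardiovascular disease. A cohort of 55-year-olds
with no history of diabetes is screened once for metabolic-syndrome risk
factors. Under the intervention strategy, risk-factor-positive subjects are
offered a community-delivered, group-format modified Diabetes Prevention
Program (mDPP) — a 12-session lifestyle course targeting modest weight loss
and increased physical activity — and enroll with probability 0.47. The
comparator, usual care, has no screening program and no intervention. The
question is the incremental cost per quality-adjusted life-year (QALY)
gained by the mDPP strategy over three years.

## State-transition model

The natural history is a six-state Markov cohort model run in monthly
cycles for 36 cycles:

* `RF_NEG` — overweight-screened adults without the metabolic-syndrome
  risk-factor cluster;
* `RF_POS_ENROLLED` / `RF_POS_NOT_ENROLLED` — risk-factor-positive, by
  program enrollment (enrollment happens once, at cycle 0, and only in the
  intervention arm);
* `STABLE_DM` — diabetes without complications;
* `COMPLICATED_DM` — diabetes with complications (neuropathy, nephropathy,
  stroke, coronary disease are pooled into this single state);
* `DEAD` — absorbing.

Risk-factor-positive subjects acquire diabetes at 10.8%/year without the
program and 4.8%/year while enrolled; risk-factor-negative subjects at
0.4%/year. The metabolic syndrome resolves (moving the subject to
`RF_NEG`) at 16.2%/year for enrolled subjects in model year 1 and at the
no-program rate of 12.1%/year otherwise; in the base case, enrolled
subjects fall back to the no-program rate in years 2–3. Risk-factor-negative
subjects become positive again at 4.0%/year; subjects who relapse after
resolving re-enter the non-enrolled positive state (there is no
re-screening or re-enrollment). Stable diabetes progresses to complicated
diabetes at 7.5%/year. All annual probabilities are converted to monthly
ones by `1 - (1 - p)^(1/12)`, the constant-hazard convention under which
twelve-fold compounding recovers the annual value exactly.

Mortality applies from every alive state as baseline age- and sex-specific
all-cause mortality multiplied, on the hazard scale, by a state-specific
relative risk (1.0 risk-factor-negative, 1.7 risk-factor-positive, 2.0
stable diabetes, 2.4 complicated diabetes):
`q_month = 1 - (1 - q_annual)^(rr/12)`. Acting on the hazard scale keeps
probabilities inside (0, 1) for any relative risk and matches the usual
semantics of a published hazard ratio. The cohort is treated as a single
pooled group: the female and male annual probabilities are mixed with the
cohort's 75% female weight before conversion, rather than running two
parallel cohorts; at these mortality levels the difference is second-order,
and the choice is isolated in `mortality_model()` so it can be revisited.
The cohort's age advances one year every 12 cycles.

Within a cycle, competing risks are ordered death-first: the monthly death
probability is applied, and the remaining transitions act conditionally on
survival with the stay-probability as the residual. This mirrors the common
decision-tree ordering; the alternative orderings differ only at second
order in the monthly probabilities.

## Rewards, discounting, perspective

Each alive state accrues one-twelfth of its annual utility (0.88
risk-factor-negative; 0.75 enrolled positive; 0.73 non-enrolled positive;
0.69 stable diabetes; 0.59 complicated diabetes) and one-twelfth of its
annual cost per cycle. Annual state costs are $616 (risk-factor-negative,
not demographically multiplied — no multipliers are published for it),
$1,296 (risk-factor-positive) and $1,684 (both diabetes states), in
year-2000 US dollars under a modified societal perspective that excludes
patients' time costs. The positive and diabetes costs are scaled by
cohort-expected demographic multipliers; complicated diabetes additionally
carries comorbidity multipliers (angina, treated hypertension, prior
MI/cardiac arrest, prior stroke, peripheral vascular disease). Whether the
comorbidity multipliers should also scale stable-diabetes cost is not
determinable from the published table layout; we apply them to complicated
diabetes only (applying them to both materially breaks agreement with the
published base case, which corroborates the choice). The cohort-expected
multiplier is the product of `1 + prevalence * (multiplier - 1)` over
conditions — exact for independent characteristics, which the
individual-level simulator verifies empirically.

The intervention arm pays one-time cycle-0 costs: screening ($35 per
positive, $32 per negative) for everyone and the $219 program fee for the
enrolled mass — about $64.84 per cohort member. Usual care pays nothing at
cycle 0.

Costs and QALYs are discounted at 3%/year with the compound-equivalent
monthly factor `(1 + r)^(-t/12)`; rewards accrue at cycle start and no
half-cycle correction is applied (the standard default of the modelling
environment this class of model is typically built in). Over a 3-year
horizon the discount convention moves the ICER by well under $400/QALY, as
the discount-sweep test demonstrates.

## Sensitivity analysis machinery

Every parameter carries a `dist_spec`: base value, examined range, and
family. One-way (tornado) analysis sets each varied parameter to its range
endpoints and records both ICERs; bars are ranked by ICER swing and
entries that never push the ICER above $7,000/QALY are flagged as minor.

The probabilistic sensitivity analysis samples all varied parameters
independently: utilities and unit costs uniform on their ranges;
probabilities and prevalences beta; relative risks log-normal; cost
multipliers normal. Ranges are interpreted as hard support for uniform and
as central 95% intervals otherwise — for the beta family the mean is
pinned to the base value and the concentration fitted numerically to the
interval (falling back to moment matching with `sd = range/3.92`), for the
log-normal the base is the median with `sdlog = (log high - log low)/3.92`,
for the normal the base is the mean with `sd = range/3.92`. This is a
calibration choice, not a published fact: the source analysis states only
the families and ranges. It keeps base values as central tendencies and is
implemented in one place (`fit_distribution()`).

The acceptability curve reports, per willingness-to-pay threshold, the
fraction of draws with positive net monetary benefit
(`lambda * dQALY - dCost > 0`). Net benefit rather than a per-draw ICER
comparison avoids the sign ambiguities of dominant and dominated draws.
Draws that fail parameter validation (possible only in distribution tails)
are redrawn and counted. The starting age is treated as an ordinary varied
parameter (uniform 45–65, rounded to whole years), as is the cohort's
female fraction, which feeds both the mortality mixture and the cost
multipliers.

## Scenario analyses

`run_scenario()` bundles the named assumption sets: stopping
metabolic-syndrome resolution after year 1 (for everyone, or for enrolled
subjects only); equalizing the risk-factor-positive utilities (the
usual-care weight is raised to the enrolled value of 0.75 — equalizing
downward instead would contradict the published QALY gain of ~0.004 for
this scenario, which the package reproduces); and two stacked worst cases
(equalized utilities + in-program diabetes risk 9.8%/year +
risk-factor-negative utility 0.77, optionally + in-program resolution cut
to 14.1%/year). Scenario point values may fall outside a parameter's
sensitivity range; the range is widened to keep the parameter set valid.

## Baseline mortality and the synthetic life table

The bundled life table (`inst/extdata/synthetic_us_lifetable.csv`) is a
synthetic Gompertz-form table — male annual death probability
`1 - exp(-a e^{b·age})` with `a = 8.4e-5`, `b = 0.085`, female hazard 0.55×
male — calibrated so that q(55) ≈ 0.009 for men and ≈ 0.005 for women,
plausible US levels around 2000. It reproduces the two features the model
actually uses: mortality rising smoothly with age and lower for women.
`load_life_table()` accepts any CSV with columns `age,sex,q_annual`
covering ages 45–70, so a real national life table can be dropped in; at
these mortality levels and a 3-year horizon the choice of vintage shifts
results by far less than the parameter uncertainty.

## The microsimulation oracle

`simulate_individuals()` is an independent individual-level implementation
of the same process: each individual draws sex, race and comorbidity flags
at baseline (independently, using the marginal prevalences — no joint
structure is published), a starting state, and then walks the same monthly
transition matrices. Costs use the individual's own sampled flags rather
than the cohort-expected multiplier, so cohort/microsimulation agreement
(within 3 Monte-Carlo standard errors at n = 200,000 in the test suite, and
across random parameter draws at smaller n) validates both the cohort
algebra and the product-form multiplier expectation. Draws are consumed in
a fixed order (initial states, the seven characteristic flags, then one
uniform per individual per cycle) so results are reproducible across
refactors.

## What the synthetic inputs do and do not show

The generator-backed tests exercise the model under the published
parameter table, a smooth synthetic life table, and independent sampling
of characteristics and parameters. They do not capture correlation between
risk factors and demographics, secular mortality trends, cause-specific
mortality, heterogeneous program adherence (adherence is folded into the
intent-to-treat effectiveness and enrollment inputs), or parameter
covariance in the probabilistic analysis — the independence assumption
tends to widen result ranges. Passing tests therefore demonstrate internal
consistency and faithful reproduction of the published analysis, not
external validity for a particular population.

## Numerical choices and problem sizes

Transition rows are renormalized only through the residual stay
probability; row sums are asserted to 1 within 1e-12 at every cycle. The
test suite runs the cohort model at its natural size (36 cycles), the
tornado over all 39 varied parameters, the probabilistic analysis at 1,000
draws, and the oracle comparison at 200,000 individuals (base case) plus
8,000-individual checks across random draws; the whole suite completes in
well under a minute on a single core. Incidence is accounted by inflow
(mass crossing into the diabetes states), not point occupancy, so deaths
after onset still count toward cumulative incidence.

## Known limitations

* The single complicated-diabetes state pools complications with one
  utility, cost and mortality risk.
* No re-screening, re-enrollment, or program effects beyond three years;
  if effects persist longer, the model understates the intervention's
  value.
* The sex mixture approximates a pooled cohort rather than sex-stratified
  traces.
* Worst-case scenario ICERs divide by QALY differences on the order of
  1e-3 and are therefore extremely sensitive to modelling conventions;
  small absolute differences in the QALY delta translate into large
  relative ICER differences.
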