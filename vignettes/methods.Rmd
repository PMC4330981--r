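---
title: "Model, calibration and uncertainty methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, calibration and uncertainty methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aitcea)
```

This vignette is the package's own account of its science: the cohort
model and its assumptions, the calibration design, the uncertainty
machinery, and the numerical choices made where the design was genuinely
open. Nothing stated here is an empirical claim beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## The decision problem

Three strategies for seasonal grass-pollen allergic rhinoconjunctivitis
are compared over nine years from the German payer perspective: a
sublingual 5-grass tablet taken pre- and co-seasonally for three
treatment years, a market mix of subcutaneous allergoid products injected
over the same period, and symptomatic treatment alone. Immunotherapy
lowers the seasonal Rhinoconjunctivitis Total Symptom Score (RTSS,
0–18): 3.26 (5-grass), 3.64 (allergoid mix) versus 4.47 (symptomatic),
values obtained from an anchored indirect comparison of placebo-controlled
trials, and halves the annual risk of developing chronic asthma
(relative risk 0.505 against an incidence of 0.0046/year).

## Cohort engine

**State space.** The engine tracks seven states: an *active* regime
(immunotherapy effect present) crossed with an absorbing chronic-asthma
flag, *discontinued* and *symptomatic-only* regimes likewise crossed with
asthma, and a single absorbing dead state. The distinction between
*on treatment* (cycles 1–3) and *completed treatment* (cycles 4+) is a
function of the cycle index, not a separate state: year-3 completers keep
the treatment effect until the horizon, so the active regime simply
persists. This matters for the half-cycle correction — because the
relabel happens at the cycle-3/4 boundary rather than inside cycle 3, the
mid-cycle on-treatment occupancy of cycle 3 equals the two-year
persistence product s₁s₂, which is what makes drug-cost accrual consistent
with a cohort that discontinues continuously through each year.

**Events.** Within a cycle, death, discontinuation and asthma onset
compete multiplicatively in that order. The ordering is a convention: at
the modelled magnitudes (annual mortality ≤ 0.00069, asthma incidence
≤ 0.0046) reordering changes any target quantity by well under 0.1%.
Discontinuation occurs only in treatment years 1 and 2 (0.29/0.28 for the
tablet, 0.41/0.34 for the allergoid mix); a discontinuing patient reverts
*within the same cycle* — via the half-cycle average — to the symptomatic
arm's symptom score, costs and asthma risk, and is never re-initiated.
Patients who develop asthma stay on their regime (the alternative,
stopping immunotherapy at asthma onset, is not modelled; the affected
share is < 1% of the cohort). Mortality is age-constant at the cohort's
entry-age values; over nine years the age trend in background mortality
would move results by far less than any reporting precision. The asthma
mortality 0.00069 is the *total* annual death probability in the asthma
state, not an increment on top of 0.00046.

**Half-cycle correction.** Every state-time accrual (costs, QALYs,
person-years) values the mean of cycle-start and cycle-end occupancy.
This is the only convention consistent with the published component
costs: valuing starts overstates and valuing ends understates treatment
time by 10–15%, while the mid-cycle treatment person-years
(0.855 + 0.6106 + 0.5112 ≈ 1.977 for the tablet) reproduce the drug-cost
component exactly. It also approximates uniformly distributed
discontinuation timing within the year, which is the natural reading of
annual persistence data.

**Discounting.** Both costs and effects discount at 3%/year with
d(t) = 1.03^−(t−1): the first model year is undiscounted. Mid-year
(t − ½) and end-year (t) conventions were considered and rejected because
only the year-1-undiscounted form reproduces the published
discounted/undiscounted QALY pair (0.081/0.090) for the same cohort.

## Valuation

**Utilities.** A year contributes
u₀ − (m/12)·k·RTSS − d·[asthma], with season length m = 3 months and
asthma decrement d = 0 by default. The linear RTSS→utility map is a proxy
for the preference-based rhinitis symptom utility index; linearity cannot
be verified from published material, but the single calibrated slope
reproduces all four published QALY contrasts to ≤ 3%, which is the
strongest evidence available to the package. The asthma decrement is
deliberately 0: its value is never published, it cancels almost entirely
from between-AIT-arm increments (< 3%), and it is exposed in the
configuration for sensitivity analysis rather than silently guessed.

**Costs.** Components accrue against mid-cycle occupancies: drug
acquisition (the tablet at €2,100.10 per 21 treated months, i.e.
€100.005/month × (4 pre-seasonal + m co-seasonal) months/year; the
allergoid mix flat at €1,449.60/3 per treatment year — one pack covers a
season regardless of its length), specialist visits (on-treatment counts
per arm; everyone else, including post-treatment completers, at 1.9
visits/year), injections (allergoid only, plus one supervised first dose
for the tablet in cycle 1), a one-off diagnostic work-up in cycle 1 for
the AIT arms booked for the full entering cohort, seasonal symptomatic
medication (lower consumption in arms with a persisting effect), and
annual asthma costs (€186.30, the 2013-indexed value). Under the societal
perspective an additional productivity stream charges patients *without*
a persisting treatment effect the calibrated per-season saving (below).
The €3.69 surcharge for long visits is carried in the configuration but
unused in the base case — the calibrated visit counts absorb whatever mix
of visit lengths underlies the published visit totals.

## Calibration

Four quantities the published analysis uses but does not print are
recovered by one-dimensional root solves (bisection on a bracketed
interval, absolute tolerance 1e-10; every map is monotone and linear, so
convergence is guaranteed), each with a closed-form oracle the test suite
checks independently:

| quantity | target | fitted value | closed-form oracle |
|---|---|---|---|
| utility slope k | undiscounted ΔQALY vs symptomatic = 0.090 | 0.05908 per RTSS point | target / (ΔRTSS · m/12 · on-effect years) |
| visit counts | undiscounted visit components €267 / €299 | 3.432 / 5.147 per treatment year | linear inversion net of off-treatment visits |
| injection count | undiscounted injection component €69 | 8.070 per treatment year | 69 / (5.11 · on-treatment years) |
| productivity saving | societal ΔC vs symptomatic €784 | €133.29 per on-effect season | (payer ΔC − societal ΔC) / discounted on-effect-year difference |

The slope is fitted *only* to the undiscounted 5-grass-vs-symptomatic
contrast; the other three published QALY contrasts (0.041, 0.081, 0.036)
are held out as validation and reproduced within 3%. The baseline
utility u₀ = 0.96997 is an optional fifth calibration against the
symptomatic arm's absolute discounted QALY total (7.235); all incremental
results are exactly invariant to it. The productivity saving corresponds
to ≈ 4.3 labour hours per season at €30.70/hour; the published sick-day
counts (3.7 vs 1.2 days) cannot be mapped to this figure by any stated
day-length convention, so the calibrated per-season saving is used and
the sick-day inputs are carried as configuration only. Calibration is a
build-time step: the fitted values are frozen in `default_config()` and
the bundled `base_case.json`, and the test suite asserts the calibrators
reproduce them (auditable, no hidden runtime fitting).

## Scenario analyses

Scenarios are pure configuration transformations. The societal scenario
adds the productivity stream to unchanged payer costs; the year-round
EQ-5D scenario replaces the seasonal symptom-utility map with annual
utilities 0.976 (persisting effect) / 0.947 (otherwise) and is therefore
independent of the calibrated slope; the short-season scenario sets
m = 2, which also removes one co-seasonal month of tablet administration
— the only reading under which the scenario's incremental cost is
consistent with per-month drug pricing. The published description of the
EQ-5D scenario assigns both AIT arms "0.947", which would make the
AIT-vs-symptomatic QALY gain vanish; this package reads that as a typo
for 0.976 (the mono-grass tablet's EQ-5D value from the cited source),
the only reading that yields a positive gain driven, as the published
discussion states, by discontinuation differences. The two remuneration
scenarios require per-setting fee-catalogue unit costs that are not part
of the shipped inputs; they error without a user-supplied table, and
`placeholder_unit_cost_tables()` provides synthetic, explicitly
non-validated tables so the machinery can be exercised.

## Uncertainty analysis

**Families.** Beta for probabilities (discontinuation, asthma incidence,
both mortalities), normal for the asthma relative risk and for treatment
efficacy expressed as the two RTSS differences versus symptomatic
treatment, gamma for unit costs and the pollen-season duration — all by
method of moments from (mean, SE), with SE = 20% of the mean where no
variance is published. Parameters are sampled independently (no
correlation structure is described for the source estimates). Normal
draws are clipped to their support with a warning; an SE too large for a
beta mean raises an error naming the parameter.

**What is not sampled, and why.** Drug acquisition prices are
administered list prices, not sampling-uncertain estimates; subjecting
them to the 20% rule would inflate the incremental-cost dispersion ~2.5×
beyond anything consistent with the published cost interval. The baseline
utility is excluded because every incremental outcome is exactly
invariant to it (and the 20% rule is moment-infeasible for a beta with
mean 0.97). The calibrated slope and resource counts are deterministic
functions of published totals and are held fixed; utility uncertainty
enters through the efficacy draws that the slope converts to QALYs.

**Efficacy dispersion.** The variances of the pooled efficacy estimates
are not published. The SE of each RTSS difference is
`efficacy_se_scale` × |mean difference|; the shipped scale 0.15336 was
produced by `calibrate_efficacy_se()` — monotone bisection on the
simulated width of the 95% interval of draw-wise incremental QALYs
(5-grass vs allergoid) at 1,000 draws — so that the interval matches the
published 0.002–0.078. This is a documented, auditable calibration, and
the routine ships so users can re-derive or re-target it.

**CEAC.** At each threshold λ the probability that an arm is most
cost-effective is the fraction of draws in which it attains the maximal
net monetary benefit. The published headline value contrasts the two
immunotherapy strategies (the two curves of the source figure), so the
acceptance computation uses `ceac(psa, 20000, arms = c("five_grass",
"allergoid"))`; the default compares all arms jointly. The one-way
deterministic analysis places each parameter at mean ± 1.96 SE (clipped
to support) and sorts by output range; with the shipped configuration the
efficacy parameter dominates incremental QALYs and the season length
dominates incremental costs, as the source analysis reports.

## Synthetic data

The trial-summary generator emulates the evidence structure behind the
indirect comparison — placebo-anchored parallel-group trials (4 + 5 by
default, 100 patients/arm), individual symptom scores normal on the RTSS
scale with a known true standardized mean difference. It deliberately
does *not* truncate scores at zero, model heterogeneity between trials,
or reproduce the nine real source trials; tests passing on it demonstrate
correct SMD arithmetic, pooling weights, anchored-contrast variance and
interval coverage, not agreement with any real trial. The
parameter-set fuzzer draws wide but admissible configurations
(probabilities in [0, 0.9], seasons 0.5–12 months) to property-test
conservation and monotonicity of the engine far from the base case.

## Problem sizes and runtime

The deterministic model is a 9-cycle, 7-state linear recursion and runs
in well under a millisecond, so the suite uses full-size runs throughout.
Stochastic checks use 1,000 PSA draws (the published simulation count),
500 synthetic meta-analyses for interval coverage, and 200 fuzzed
configurations for conservation, sizes chosen so each property is tested
at its published scale while the whole suite stays interactive.

## Known limitations

Adverse events, hospitalizations and new sensitizations are outside the
model, as in the source analysis. Absolute QALY *levels* depend on the
optional baseline-utility calibration; only increments are primary
outputs. The remuneration scenarios cannot be validated without the fee
catalogues. The linear symptom-utility proxy and the independence of PSA
parameters are modelling conventions inherited from the source analysis,
not estimable facts; both are surfaced as explicit configuration rather
than buried constants.
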