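---
title: "A lifetime Markov model of adjuvant endocrine therapy in early breast cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lifetime Markov model of adjuvant endocrine therapy in early breast cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endocea)
```

## The decision problem

Postmenopausal women with estrogen receptor positive (ER+) early breast
cancer receive five years of adjuvant endocrine therapy after surgery. The
three strategies compared are five years of tamoxifen (the low-cost
standard), five years of the aromatase inhibitor letrozole, and a switch
regimen (tamoxifen for 2–3 years, letrozole to year five). Aromatase
inhibitors reduce recurrence but cost roughly ten times more per day as
generics, and they trade a lower endometrial-cancer risk against a higher
fracture risk. `endocea` projects lifetime costs (2016 CNY, Chinese
health-care payer perspective) and quality-adjusted life-years (QALYs) for
the three strategies, and summarises the trade-off as incremental
cost-effectiveness ratios (ICERs) judged against a willingness-to-pay
threshold of ¥171,000/QALY (three times per-capita GDP).

## Model structure

The cohort starts disease-free at age 57.3 and is redistributed monthly
over six exclusive health states — disease-free, local recurrence,
contralateral recurrence, distant recurrence, endometrial cancer, and
death — until death or age 100. Bone fracture is a temporary event: it
leaves the woman disease-free but flagged, with a one-time cost and a
persistent utility interaction; at most one fracture per woman is modelled,
and fractures and endometrial cancer arise from the disease-free state
only. Local and contralateral recurrence feed distant recurrence (never
each other); distant recurrence and endometrial cancer carry their own
monthly death probabilities; background mortality from a female life table
applies additively in every state. Deaths are tracked by cause.

Baseline (tamoxifen-arm) recurrence risks are parametric survival laws of
the form \(S(t) = \exp(-\lambda t^{\gamma})\) on the model clock, in
months: exponential for local and distant recurrence, Weibull for
contralateral recurrence. Progression after a local or contralateral
recurrence follows Weibull laws on the *state-entry* clock; occupancy of
those states is therefore partitioned exactly by months since entry
(a convolution over entry cohorts rather than an approximate tunnel),
because with shape \(\gamma \neq 1\) time-in-state changes the hazard
materially.

Letrozole-containing strategies modify the baseline monthly probabilities
through risk ratios applied on the hazard scale, \(1 - (1-p)^{RR}\), which
preserves probability bounds and coincides with \(p \cdot RR\) to first
order at these magnitudes. Recurrence risk ratios apply from randomisation
for the whole lifetime. Side-effect risk ratios (endometrial cancer 0.33,
fracture 1.42) begin when aromatase-inhibitor exposure begins — month 0 for
the 5-year arm, the switch month for the switch arm — and also persist for
life by default. That onset rule is the package's own reading: the
published cumulative endometrial-cancer probabilities (1.97% tamoxifen,
0.70% letrozole ≈ 0.33×, 0.88% switch, intermediate) are arithmetically
consistent only with side-effect risk ratios starting at the switch. A
`side_effect_duration = "treatment"` option confines them to the exposure
months instead.

Competing monthly risks are combined by converting each probability to a
rate, summing, converting the total back to an exit probability and
apportioning it proportionally to the rates — the standard rate-additive
competing-risk construction, applied uniformly in every state.

## Economics

Costs and QALYs are discounted at 5% per year, applied per monthly cycle
as \((1.05)^{-t/12}\); life-years are reported undiscounted (the published
QALY/life-year pair is only arithmetically consistent on that convention;
discounted life-years are also computed). Drug cost is daily price ×
30.4375 (365.25/12) while the schedule is active and the woman is
disease-free. Utilities: disease-free 0.94 less a 0.01 endocrine-therapy
decrement while on therapy, regional recurrence 0.78, distant 0.53,
endometrial cancer 0.83. A fracture combines with the disease-free weight
through the anchored joint form
\(U_{ij} = U_{min} - U_{min}(1-U_i)(1-U_j)\), \(U_{min}=\min(U_i,U_j)\),
implemented exactly as published; it is unusual (anchored at the worse
utility rather than multiplicative), so the conventional multiplicative
model is available behind `joint_utility_model = "multiplicative"` for
sensitivity — no intent is guessed.

**Recurrence costing.** The published input table lists both a large
first-month management cost for each recurrence type (¥75,421
locoregional, ¥83,008 distant) and a monthly cost for subsequent months
(¥865, ¥888). Charging the first-month value at state entry yields
lifetime costs around three times the published totals; charging the
monthly value in every month, entry included, reproduces the published
costs and ICERs to within a few percent, and the published branded-price
ICERs independently confirm the remaining costing conventions. The default
is therefore `recurrence_entry_cost = "monthly"`; the tabulated first-month
premium is available as `"first_month"` for users who prefer the input
table's literal reading. One-time fracture (¥25,552) and
endometrial-cancer (¥17,138) costs attach, discounted, at the incidence
cycle.

No half-cycle correction is applied by default: with monthly cycles the
correction is well under the reporting precision (a
`half_cycle_correction` option exists and moves QALYs by <0.02). The
switch month defaults to 30, the midpoint of the 2–3-year switch window,
and is a config key.

## Background mortality and the synthetic life table

The reference analysis uses 2009 national female life tables, which are
not redistributable with the package. `read_life_table()` ingests any
`age,qx` CSV for exact-reproduction runs. For self-contained use and for
the test suite, `synth_life_table()` generates a Gompertz–Makeham table,
\(q_x = 1 - \exp(-(c + \alpha e^{\beta x}))\), with defaults
`makeham = 2e-4`, `alpha = 9e-6`, `beta = 0.11`. These were calibrated
once, to a remaining female life expectancy at age 57 of 25.1 years — the
bottom of the 25–27-year band this package targets for a
middle-income-country female population, chosen because a direct fit to
WHO-style 2009 Chinese female death probabilities (q55 ≈ 0.005,
q75 ≈ 0.038, q85 ≈ 0.11) suggests the real table is, if anything, slightly
heavier. Mortality lookup uses `floor(age)` (annual table resolution);
ages beyond the last row reuse the last row until the horizon age, where
the model closes.

What the synthetic table does *not* emulate: the exact age profile of the
2009 tables (a two-parameter senescence law is smoother than a real
table), cohort mortality improvement, and any excess non-cancer mortality
of breast-cancer survivors (deliberately ignored, matching the reference
analysis). Consequently reproduction-grade agreement is expected for
quantities dominated by the first two decades (costs, QALYs, ICERs, all
within ~6% here) but not for tail-sensitive quantities: undiscounted
life-years run ~5% high and the lifetime first-recurrence probability
~13–16% low relative to the published values, and the age at which the
5-year-letrozole ICER crosses ¥171,000 lands at 80 rather than 76–79.
Tests passing on the synthetic table validate the model mechanics and the
published-value neighbourhood, not exact reproduction of results computed
from the real table.

A further counting caveat: the package reports lifetime breast-cancer
recurrence as the probability of a *first* recurrence per woman (exits
from disease-free); the published 57.63% lies between that definition and
a sum-of-entries convention that double-counts women whose local or
contralateral recurrence later progresses, so part of the gap is
definitional, not mortality-driven.

## Sensitivity analyses

*One-way (tornado):* `owsa()` re-evaluates the ICER of a strategy pair at
the lower and upper tested limit of each ranged input, including starting
age (27–79, the cohort age range) and the discount rate (0–8%, a
conventional band; the source table lists no range for it), and sorts by
bar width. *Age sweep:* `age_sweep()` recomputes ICERs over starting ages.
*Probabilistic:* `draw_psa()` samples all uncertain parameters jointly —
beta for probabilities and utilities (method of moments, mean = base,
sd = range/3.92, the tested range read as a 95% interval), lognormal for
costs, risk ratios and survival scales (median = base, 95% interval from
the range; ratio parameters are conventionally lognormal even though the
source names only beta and lognormal). Structural settings (start age,
discount rate) are never sampled. `run_psa()` shares each draw across
strategies (common random numbers) so incremental contrasts reflect
parameter uncertainty only, and is bit-reproducible given its seed.
`ceac()` converts draws to cost-effectiveness acceptability curves via
net monetary benefit; `ceac_multiway()` gives the probability each
strategy is optimal.

One published PSA quantity is *not* reproduced and deliberately left so:
the ~90% probability that 5-year letrozole is cost-effective versus
tamoxifen at ¥171,000/QALY. Under common random numbers with ranges read
as 95% intervals, every sampled recurrence risk ratio stays below 1 and
the probability is 1.0; reading the ranges as mean±SD instead gives 0.95
versus tamoxifen but degrades the versus-switch probability (0.64 against
a published ~70%, which the default reading matches at 0.72). No reading
reconstructs both published values, so the declared-interval convention is
kept rather than tuned.

## Numerical choices and degenerate inputs

Survival-to-probability conversion uses cumulative-hazard differences
(`1 - exp(-λ((t+1)^γ - t^γ))`) rather than survival ratios for numerical
stability; `log1p`/`expm1` guard the probability–rate pair; a terminal
life-table row with `qx = 1` is represented as a just-sub-unity monthly
probability so the rate algebra stays finite; zero total exit rate yields
a pure self-loop; degenerate PSA ranges (the endocrine disutility's
0.01–0.01, or ranges shrunk to zero) reproduce the base value exactly.
One published range (progression after local recurrence,
λ = 0.0458 with tested range 0.004498–0.023713) does not bracket its own
base value; it is kept exactly as published — the one-way analysis
evaluates the printed endpoints, and the lognormal PSA anchors at the base
as median with spread from the printed width, so nothing becomes
infeasible.

## Problem sizes used by the tests

The test suite runs the full 513-cycle cohort (~55 ms per strategy), a
1,000-draw PSA for the acceptability probabilities, and cross-validates
the cohort engine against an independent 200,000-walker individual-level
micro-simulation at cycles 60, 120 and 240 on three parameter sets
(agreement within three binomial standard errors). These sizes were chosen
to keep Monte Carlo error well below every tolerance being checked.

## Worked example

```{r}
lt <- synth_life_table()
bc <- base_case(default_params(), lt)
bc$outcomes$ai_5yr
bc$comparisons$ai_5yr_vs_tamoxifen
```

## Known limitations

No tumour-stage or nodal heterogeneity; no recurrence hazard cap after
trial follow-up (the fitted laws extrapolate for life); fractures and
endometrial cancer only from the disease-free state; no transitions
between local and contralateral recurrence; no indirect costs, currency
conversion or inflation adjustment; no expected-value-of-perfect-
information analysis.
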