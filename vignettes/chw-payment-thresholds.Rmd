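---
title: "Estimating break-even Medicaid payment rates for CHW programs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating break-even Medicaid payment rates for CHW programs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chwpay)
```

## The model and its assumptions

`chwpay` treats the financing question as a break-even accounting problem,
simulated geography by geography. The unit of analysis is one full-time
community health worker (CHW). Their employer must cover three cost
streams, all expressed in undiscounted 2023 US dollars over a one-year
horizon (a CPI multiplier, `adjust_to_2023_usd()`, maps older source-year
dollars onto that base; the factor is a user input because each input
stream carries its own base year):

1. **Labor** — the CHW's hourly wage over 2080 paid hours.
2. **Supervision** — one supervisor's wage allocated across the team:
   a Registered Nurse care manager shared 1:8 in the base case, a
   Master's-level social worker shared 1:6 in the substitution scenario.
   Supervision is modelled as wage allocation only; any
   supervisor-attributable overhead is assumed to already sit inside the
   per-CHW-hour overhead ledger, which is reported as a single per-CHW
   figure in the source surveys.
3. **Overhead** — five categories per CHW work-hour: equipment, software,
   transportation, office space, and employee benefits.

Revenue comes from one of two Medicaid contract forms. Under
fee-for-service, the program bills a fixed rate per 30-minute visit
(billing code 98960), in person or virtual; under capitation it receives a
per-member-per-month rate for each of the 65 patients concurrently on the
panel. The break-even threshold is the rate at which revenue exactly
equals the monthly cost — a minimum, with no margin, risk adjustment or
payer-mix modelling.

Visit capacity converts paid time into billable volume. With a 1:3
in-person-to-virtual mix, a quarter of visits carry the geography's full
round-trip travel time, so a month of bookable hours supports
`(2080/12 × productive_fraction) / (0.5 + 0.25 × travel_time)` visits.
Two modelling choices deserve emphasis:

* **Travel opportunity cost is realized through capacity, not the
  ledger.** The transportation overhead category is treated as vehicle and
  commute dollars; the wage value of time in transit enters solely as
  reduced visit capacity. Charging it in both places would double-count
  the same hour. The sources are ambiguous on this point, so
  `service_model(travel_opportunity_in_overhead = TRUE)` moves the wage
  charge into the monthly cost instead, with capacity then ignoring
  travel — one route or the other, never both.
* **`productive_fraction` defaults to 1**: every paid hour is a visit or
  travel hour. This is the most generous assumption — any administrative
  deduction raises the FFS threshold proportionally — and is exposed as a
  parameter rather than guessed, since no utilization factor is published
  for these programs.

Enrollment duration (6 months per patient on average) affects reporting
only: a 65-patient panel turns over into `65 × 12/6 = 130` patients served
per CHW-year. PMPM revenue is billed per concurrent member-month, so the
threshold itself is unaffected.

## Key parameters

| Parameter | Default | Units | Where |
|---|---|---|---|
| `annual_hours` | 2080 | paid h/year | `staffing_plan()` |
| `supervisor_ratio` | 8 (RN), 6 (MSW) | CHWs per supervisor | `staffing_plan()` |
| `panel_size` | 65 | concurrent patients | `service_model()` |
| `enrollment_months` | 6 | months | `service_model()` |
| `visit_duration` | 0.5 | hours | `service_model()` |
| `inperson_share` | 0.25 | fraction | `service_model()` |
| `productive_fraction` | 1.0 | fraction | `service_model()` |
| `n_draws` | 10,000 | draws | `sim_config()` |
| `ci_level` | 0.95 | fraction | `sim_config()` |
| `truncation_floor` | 0.01 | $ | `sim_config()` |

## Uncertainty propagation

Each uncertain input — the CHW wage, both supervisor wages, and the five
overhead components — is sampled independently from a normal distribution
around its geography-specific mean and sd. Cross-input covariation is
represented through geography-level stratification (wages and overhead
are jointly high or low *because* each geography carries its own means),
not through an estimated covariance matrix, which the source surveys do
not provide. Numerical choices:

* **Truncation by resampling.** Draws below $0.01 are redrawn rather than
  clipped: clipping would put point mass at the floor and bias means.
* **Percentile intervals.** The 95% credible interval is the empirical
  2.5th–97.5th percentile span of the draws (quantile type 7), not a
  normal approximation — the draw distribution of pooled thresholds is
  right-skewed whenever overhead is.
* **Seeding.** One master seed; geography `i` draws from the substream
  seeded `(seed × 1000003 + i) mod (2^31 − 1)`. Results are therefore
  bit-reproducible, independent of geography order or subsetting, and the
  supervisor-substitution scenario reuses the identical draws (every
  uncertain field is always sampled, in a fixed order, whichever plan
  consumes it), so scenario contrasts are purely structural.
* **Aggregates** (state, metro, non-metro, national) are means of
  per-draw thresholds across geographies within each draw, unweighted by
  default; employment weights are supported (`use_weights`). The
  published analysis does not state its weighting, so the simpler default
  is documented rather than assumed.
* Fractional visits are never rounded: thresholds are rates, not
  schedules, and the break-even identities (`FFS × visits = monthly cost`,
  `PMPM × panel = monthly cost`) hold to machine precision in every draw.

The panel sweep rescales the baseline by the inverse-panel law
`rate(P') = rate(P) × 65/P'`, applied to the point value *and to every
stored draw*, so CI bounds rescale by exactly the same factor. For FFS
this assumes demand-limited volume — visits proportional to panel at fixed
per-patient intensity — which is the reading consistent with the published
endpoint pair ($230.72 at panel 15, $34.61 at panel 100 from a $53.24
baseline); the engine warns when demand-implied volume would exceed
capacity.

## What the synthetic generator emulates

Real inputs are per-geography tables from the BLS OEWS survey (wages) and
commercial surveys (overhead), which cannot be redistributed here. The
generator (`generate_geographies()`) reproduces their *statistical
structure*, with national targets matching the published descriptives:

* CHW wages from a range-truncated normal, mean $23.51/h over the printed
  national range $15.90–$31.61 (supervisors: RN $39.88, MSW $29.37
  analogously). The printed wage range is near-symmetric, hence normal.
* Overhead totals from a log-normal calibrated so the arithmetic mean is
  $43.65/h; the printed range $19.21–$196.41 around that mean is strongly
  right-skewed, hence log-normal (cross-geography log-sd 0.55).
* A beta-distributed transportation share of overhead, mean 0.651.
* Travel times of 0.75 h (metro) vs 1.15 h (non-metro) ± 0.20 h. These
  are a **calibration, not a survey fact**: they are set so that the
  capacity-implied national FFS under default settings lands near the
  published $53.24.
* Within-geography sds — not published — default to 25% of the wage mean
  and 40% of each overhead component mean, chosen once to give per-
  geography credible intervals of the same order as the published state
  intervals. They are flagged as assumptions.

What it does **not** emulate, and what passing tests therefore do not
show: real OEWS area definitions or any actual state's values; a
metro/non-metro wage gradient (real metro wages run higher, which is why
published FFS minimums are slightly higher in metro areas, while the
synthetic contrast is driven by travel time alone and runs the other way);
and the exact pooled shape behind the published national intervals. The
published national means are also not mutually consistent with a single
composite geography — summing the national mean wage, supervision and
overhead gives a monthly cost near $12,505, while the published PMPM of
$140.18 × 65 implies about $9,112 — because national figures average
per-geography results whose travel times and sds live in unpublished
per-area tables. The engine reproduces any such table exactly when a user
supplies it; on synthetic data only the structural properties (identities,
monotonicity, scaling laws, CI calibration) and the explicitly calibrated
FFS level are meaningful.

## Problem sizes

The test suite exercises the identities on 500 synthetic geographies ×
1,000 draws and the credible-interval calibration at 10,000 draws; the
analysis workflow runs 104 geographies (52 states × metro/non-metro) at
the full 10,000 draws, matching the published draw count. All runs are
single-threaded and complete in seconds.

## Known limitations

* Thresholds are minima: no margin, reserve, payer mix or risk adjustment.
* Supervision archetypes are limited to RN and MSW; the substitution
  scenario changes wage and ratio only, leaving the overhead ledger fixed,
  so it understates any supervisor-specific overhead differences.
* Normal input sampling can be a poor fit for strongly skewed
  within-geography wage distributions; only the cross-geography layer is
  explicitly skewed.
* The CPI adjustment is a single scalar per run, not a per-stream table.
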