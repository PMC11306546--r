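# chwpay

Break-even Medicaid payment thresholds for community health worker (CHW)
programs.

## The problem

CHW programs — lay health workers from a patient's own community providing
support, education and navigation, often through home visits — are
increasingly financed through Medicaid, either as fee-for-service (FFS)
payments per 30-minute visit (billing code 98960) or as capitated
per-member-per-month (PMPM) payments for each patient on a CHW's panel.
Unlike clinic-based care, CHW programs carry heavy transportation time and
cost, mobile equipment, and flexible supervision, and the payment rates
states post are rarely grounded in a cost accounting of what a sustainable
program actually spends. `chwpay` implements a geography-stratified
microsimulation that answers: *what is the minimum FFS or PMPM rate at
which revenue exactly covers the full cost of employing one CHW?*

It is written for health-economics analysts and state program staff who
have (or can assemble) per-geography wage and overhead tables, e.g. from
the BLS Occupational Employment and Wage Statistics survey.

## The model

For one full-time CHW working `H = 2080` paid hours/year in geography `g`:

```
annual cost  C_g = w_g * H                 (CHW labor)
              + s_g * H / r                (supervisor wage, shared 1:r)
              + (e_g + f_g + t_g + p_g + b_g) * H   (overhead per work-hour:
                                            equipment, software, transportation,
                                            space, benefits)
monthly cost M_g = C_g / 12
```

Visit capacity follows from the visit mix: each visit takes `d = 0.5` h,
and the in-person fraction `q = 0.25` (a 1:3 in-person-to-virtual ratio)
additionally carries the round-trip travel time `τ_g`:

```
V_g = (H/12) / (d + q * τ_g)       visits per month
```

The two break-even thresholds, for a panel of `P = 65` concurrent patients:

```
FFS_g  = M_g / V_g        ($ per 30-min visit)
PMPM_g = M_g / P          ($ per member per month)
```

Uncertainty is propagated by sampling every uncertain input (wages,
overhead components) 10,000 times from independent normal distributions
around its mean and sd (truncated below at $0.01 by resampling), computing
both thresholds within every draw, and reporting the draw mean with an
empirical 95% percentile credible interval. Aggregates (state, metro,
non-metro, national) average per-draw thresholds across geographies within
each draw. Two sensitivity analyses are built in: substituting the RN care
manager supervisor (1:8) with an MSW supervisor (1:6), and sweeping the
panel size from 15 to 100 by the inverse-panel law
`rate(P') = rate(P) * P / P'`.

## Worked example

```r
library(chwpay)
g <- fixture_national()          # national composite: CHW $23.51/h, RN $39.88/h,
                                 # overhead $43.65/h (65.1% transportation)
total_cost(g, staffing_plan())
#> <cost_breakdown> per CHW, 2023 USD
#>   labor            48900.80 /yr
#>   supervision      10368.80 /yr
#>   ...
#>   total           150061.60 /yr = 12505.13 /month
point_thresholds(g)
#> <threshold_estimate> US-NATIONAL
#>   FFS  $53.21 per 30-min visit (95% CI 53.21, 53.21)
#>   PMPM $192.39 per member-month (95% CI 192.39, 192.39)
```

$53.21 is what a 30-minute visit must pay, at the composite's 0.95 h
travel time and 235 visits/month, for revenue to cover the $12,505 monthly
cost; the PMPM equivalent spreads that cost over the 65-patient panel.

The full analysis is a four-step workflow:

```sh
Rscript analysis/01_synthesize_inputs.R   # synthetic 52-state input table
Rscript analysis/02_baseline_costs.R      # deterministic worked example
Rscript analysis/03_uncertainty.R         # 10,000-draw Monte Carlo + aggregates
Rscript analysis/04_sensitivity.R         # supervisor swap + panel sweep
```

Each step prints what it found and writes its tables under `results/`.
Real per-geography tables can be substituted for the synthetic ones: any
CSV in the documented schema (see `?load_geography_inputs`) drives steps
3–4 unchanged.

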