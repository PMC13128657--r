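# dipburden

Quantifying the economic burden of hospital-acquired infections (HAIs) on
cancer inpatients settled under China's **Diagnosis-Intervention Packet
(DIP)** case-based payment model.

## The problem

Under DIP, every discharge is grouped by *principal diagnosis + primary
procedure* into a category carrying a standard payment. The hospital's
financial outcome for an episode is the **DIP payment differential**

```
differential = DIP standard payment − actual hospitalization cost
```

(positive = surplus, negative = loss). An HAI — an infection with onset
≥ 48 h after admission — inflates cost and length of stay, and therefore
pushes the differential toward a loss that the raw cost comparison cannot
express. Estimating that attributable burden is confounded twice over:
sicker patients are both more infection-prone and more expensive, and the
longer a patient stays, the more days they are at risk (*time-dependent
bias*), so naive case–control designs overstate the attributable stay.

`dipburden` implements the full analysis chain for hospital-epidemiology
and health-insurance analysts:

* **Synthetic cohort generator** (`generate_cohort()`) — inpatient episodes
  with DIP-category-specific log-normal costs and stays, a per-at-risk-day
  infection hazard (days 2..LOS), and *injected, known-magnitude* infection
  effects, so every estimator can be validated by parameter recovery.
* **CACI scoring** (`caci_score()`, `add_caci()`) — Charlson age-comorbidity
  index from ICD-10 codes (Quan-2005 mapping, original weights, shipped as
  an editable text resource), with the high-risk (> 3) / low-risk (≤ 3)
  strata used as matching criteria.
* **Three matching designs** — exact 1:1 (`exact_match()`), propensity-score
  nearest-neighbour with a 0.2-SD logit caliper (`propensity_match()`), and
  **risk-set matching** (`risk_set_match()`, the primary design): each case
  infected on day T1 is matched to a patient still hospitalized and *not yet
  infected* at T1, which removes the time-dependent bias.
* **Nonparametric comparison engine** — Mann–Whitney U (exact for small
  tie-free samples), Kruskal–Wallis, χ², and the **Hodges–Lehmann median
  difference** (median of all pairwise case-minus-control differences) with
  its distribution-free Moses confidence interval (`compare_groups()`).
* **Payment-differential GLM** (`fit_differential_glm()`) — Gaussian
  identity-link model of the differential on the matched sample with
  heteroskedasticity-consistent (HC1 sandwich) standard errors.
* **Orchestration** (`run_full()`) — cohort → CACI → profiles → category
  concentration report → classification strata → matched analyses → GLM,
  all written as CSVs with a run manifest; bit-reproducible under a seed.

## Worked example

```r
library(dipburden)

cfg <- cohort_config(n_patients = 20000, seed = 7)   # defaults: 0.4% incidence,
co  <- generate_cohort(cfg)                          # +$5,031 cost, +$799 dx, +9 d
n_cases <- length(unique(co$infections$episode_id))
incidence_rate(n_cases, 20000)
#> [1] 0.39

ep <- add_caci(co$episodes)
ma <- run_matched_analysis(ep, co$infections, model = "risk_set", seed = 7)
ma$cohort
#> Matched cohort (risk_set): 78/78 cases matched 1:1, 0 unmatched
ma$comparisons$dip_differential
#> dip_differential
#>   cases:    -5384.99 (-6939.76, -4725.11), n=78
#>   controls: -146.57 (-1050.52, 629.96), n=78
#>   MD -5455.99 (95% CI -5999.30, -4916.93), Z = -9.563, p = 1.145e-21
```

The cohort's 0.39% incidence matches the generator's calibration target.
After risk-set matching, infected episodes show a median DIP differential
deep in deficit while their matched controls sit near break-even; the
Hodges–Lehmann median difference of −$5,456 (95% CI −5,999 to −4,917)
covers the injected truth of −$5,031 (the generator's standard payments are
category-constant, so the injected cost inflation maps one-to-one onto the
differential). The GLM on the same matched sample:

```r
g <- fit_differential_glm(ep, co$infections, ma$cohort)
g$coefficients[g$coefficients$term == "haiyes", ]
#>    term         B robust_se   ci_low  ci_high     p_value
#>  haiyes  -5632.98    602.09 -6813.05  -4452.9 8.30436e-21
```

A full report bundle (CSV tables plus manifest) comes from
`run_full(analysis_config(...))`, or from the shell via the thin wrapper:

```sh
Rscript inst/scripts/run_pipeline.R --out run1 --seed 7 --n 20000
```

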