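---
title: "Estimating the DIP payment burden of hospital-acquired infections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the DIP payment burden of hospital-acquired infections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dipburden` estimates what a hospital-acquired infection (HAI) costs a
hospital that is paid per case under the Diagnosis-Intervention Packet
(DIP) model. This vignette explains the statistical machinery, the
assumptions behind it, the design choices that were genuinely open, and
what the synthetic-cohort validation does and does not demonstrate.

## The estimand and why matching is needed

For each discharge the settlement outcome is the DIP payment differential,
`standard payment − actual cost`: positive is a surplus, negative a loss.
The target quantity is the shift in cost, diagnostic cost, length of stay
(LOS) and differential *attributable* to an HAI (onset ≥ 48 h after
admission, day 0 being admission day, so onsets on days ≥ 2 qualify).

Two biases dominate naive infected-vs-uninfected comparisons:

1. **Confounding** — infection risk rises with case complexity, which also
   drives cost. The package therefore matches on DIP category (which fixes
   diagnosis + procedure and hence the payment standard), sex, age within
   5 years, and the Charlson age-comorbidity index (CACI) risk stratum
   (high when CACI > 3).
2. **Time-dependent bias** — every extra hospital day is another day at
   risk, so infected patients have longer stays *even absent any causal
   effect*. Comparing cases to never-infected controls attributes that
   length-bias to the infection. **Risk-set matching** removes it: a case
   infected on day T1 is matched to a patient still hospitalized on T1 and
   not yet infected at T1 (patients infected later remain eligible — that
   is the point of the design). Exact matching and propensity-score
   matching are provided as comparison designs; the package's simulations
   show the risk-set LOS estimate is consistently the smallest of the
   three, which is the expected direction of the bias correction.

Matched groups are compared with the Mann–Whitney U test and summarised by
the Hodges–Lehmann (HL) median difference — the median of all
case-minus-control pairwise differences — because settlement data are
heavily right-skewed and a difference of medians is neither a median
difference nor equipped with a distribution-free interval.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `max_age_difference` | 5 | years | standard clinical matching width |
| CACI stratum cut | score > 3 | — | high/low comorbidity risk split |
| PSM caliper | 0.2 | SD of logit propensity | the conventional caliper |
| `alpha` | 0.05 | — | two-sided throughout |
| exchange rate | 7.12 | CNY per USD | 2024 annual average |
| reporting precision | 2 | decimals, half-up | settlement ledger convention |
| `daily_infection_hazard` | calibrated | probability/day | solves for 0.4% episode incidence |
| `cost_inflation` | 5031.01 × 7.12 | CNY | injected HAI cost effect |
| `diagnostic_inflation` | 798.81 × 7.12 | CNY | injected diagnostic effect |
| `los_extension` | 9 | days | injected stay extension |
| `mdro_escalation` | 1.942 | × per extra MDRO type | see below |

## What the generator emulates

`generate_cohort()` draws episodes from an eight-category DIP catalogue:
five surgery-heavy oncology categories (esophagectomy, gastric surgery,
two rectal-resection variants, radical hysterectomy) whose baseline cost
and stay medians sit in the range reported for infection-concentrated
categories, plus three high-volume chemotherapy/radiotherapy categories
that dominate discharges at a cancer centre. Within a category, baseline
LOS is a discretised log-normal and cost a log-normal whose log-mean moves
with log-LOS (elasticity 0.5), so longer stays are costlier before any
infection — this is what makes the time-dependent bias real in the
simulation. The standard payment equals the category's baseline median
cost, so uninfected differentials centre near zero and the injected cost
inflation maps one-to-one (with a minus sign) onto the differential.

Infection is a Bernoulli trial on each at-risk day 2..LOS (geometric
waiting time). The default hazard is found by numerically inverting
`P(infected) = E[1 − (1 − h)^(LOS−1)]` over the catalogue's stay mixture to
hit an episode-level incidence of 0.4%, the order observed in
well-controlled specialised cancer centres. Multiple events per stay are
possible; effects are injected once per infected episode. MDRO type counts
given infection default to 0.745/0.216/0.024/0.015 over 0/1/2/3+ types.
The escalation multiplier 1.942 per additional type makes a ≥ 3-type stay
lose ≈ 1.942² = 3.77 times the base effect — chosen so that, with a
2,021-USD-scale base effect, the ≥ 3-type dummy lands on the
−5,600-USD scale, reproducing the reported ordering in which the
multi-resistant effect dwarfs the average HAI effect.

Two generator details deserve emphasis:

* **Why recovery is unbiased here.** Because the infection trial on each
  day does not look ahead, case status at T1 is independent of the
  *remaining* stay given survival to T1. Risk-set matching therefore
  compares groups with identical baseline-LOS distributions and the HL
  estimator recovers the injected shifts at nominal coverage. This is a
  property of the geometric hazard; real infection hazards need not be
  memoryless, and real recovery may be less clean.
* **Unrecorded wound grades.** 4% of operated stays carry no wound class.
  Real registries have exactly this missingness; without it the wound-class
  dummies equal the surgery indicator summed and the full covariate set is
  unidentifiable. The very large standard errors that the matched-sample
  GLM puts on the surgery and wound terms are the visible footprint of
  this near-collinearity.

What the generator does **not** emulate: mortality and censoring by death,
readmission, community-acquired infection (excluded at intake), seasonal
admission patterns, correlated comorbidity profiles (Charlson codes are
sampled independently given the category's primary malignancy), and any
within-category heterogeneity of the payment standard. Passing recovery
tests therefore validates the estimators under these stated conditions,
not the clinical magnitudes themselves.

## Numerical and procedural choices

* **Mann–Whitney p-values**: exact null distribution when both sides have
  ≤ 20 observations and the pooled sample is tie-free; otherwise the
  tie-corrected normal approximation *without* continuity correction,
  which preserves the k = 2 identity `H = Z²` with the tie-corrected
  Kruskal–Wallis statistic. The standardised Z is always reported.
* **HL interval**: the rank-based Moses interval on the sorted pairwise
  differences; the cut uses exact Mann–Whitney quantiles for small
  samples, else the normal approximation, and never interpolates between
  order statistics (conservative). Simulated coverage at n = 50 per arm is
  93–97%.
* **Medians/quartiles**: linear interpolation between closest ranks
  (`quantile` type 7), fixed for reproducibility.
* **Greedy matching, not optimal assignment**: cases are processed in
  ascending T1 (risk-set) or id order (exact), controls chosen by smallest
  age difference with id tie-breaks, without replacement. Greedy sequential
  construction is the standard risk-set procedure and is reproducible; an
  optimal-assignment variant would change pairings only at ties.
* **Case-as-control conflicts**: a later-infected patient already chosen
  as control is retained as a control and dropped from the case list, with
  a logged message. First-assignment-wins keeps the construction
  sequential and honest to "not yet infected at T1".
* **Caliper convention**: 0.2 × SD of the *logit* propensity (not an
  absolute probability caliper); the propensity model uses age, sex and
  CACI stratum, with DIP category enforced exactly during matching rather
  than entered as high-cardinality dummies (which invites separation).
  Perfect separation is detected and reported with advice to fall back to
  exact matching.
* **"Robust" GLM**: Gaussian family with identity link — so point
  estimates are ordinary least squares — and HC1 sandwich standard errors,
  with normal-quantile intervals (`B ± 1.96·SE`); a t-reference is
  available behind a flag. The matched-pair structure is deliberately not
  modelled with a random effect: the reported design fits a plain GLM on
  the matched sample, and we reproduce that, noting it as a limitation.
* **Rounding**: half-up to 2 decimals only at reporting boundaries;
  internal arithmetic at full precision.
* **Determinism**: one master seed spawns per-stage child seeds
  (demographics, baseline draws, infection process), so toggling one stage
  does not perturb the others; identical configs give byte-identical CSVs.

## Problem sizes used in validation

The test suite recovers the injected magnitudes on 100 replicates of
20,000-episode cohorts at the calibrated 0.4% incidence (~80 cases per
replicate, HL intervals covering each injected truth in ≥ 90% of
replicates), estimates the GLM HAI coefficient across 200 replicates
(mean within Monte-Carlo error of the injected effect), checks the
risk-set matcher against a brute-force eligibility oracle on 50-episode
cohorts, the HL estimator against full pairwise enumeration up to
200 × 200, null type-I error over 5,000 replicates at 30 per arm, and the
bias direction (risk-set LOS difference ≤ exact-match LOS difference) over
200 replicates of 600-episode high-hazard cohorts. These sizes were chosen
so each property is measured with useful precision while the whole suite
runs in minutes.

## Known limitations

* The DIP grouping engine itself is out of scope: the DIP category is an
  input label, and standard payments are taken as given.
* The Charlson ICD-10 mapping is the published Quan-2005 algorithm with
  original weights; institution-specific code lists can be dropped in via
  `charlson_map(path)`, and age points (one per decade from 50, capped at
  4) follow the common convention.
* Effects are injected once per infected episode; frequency gradients in
  the classification report arise only through MDRO correlation, so the
  per-event dose-response of real data is only partially emulated.
* HL median differences and GLM coefficients answer different questions
  under skew (a median contrast vs an adjusted mean contrast); their
  disagreement on real settlement data is expected, not an error.
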