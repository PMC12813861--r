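---
title: "Projecting ambulance demand under demographic change: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting ambulance demand under demographic change: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(easproj)
```

## The projection model

`easproj` projects yearly emergency ambulance service (EAS) demand decades
ahead for a city whose age-gender composition is changing faster than its
total population. The method is deliberately simple and fully transparent —
the kind of model a fire department or health bureau can audit line by line.

**Weighting factors.** For an age band $a$ and sex $g$, the population-change
index between a base year and a target year is
$$W_{a,g} = \frac{P_{\text{target}}(a,g)}{P_{\text{base}}(a,g)},$$
the elementwise ratio of two population pyramids (`compute_weights()`).
Official pyramids are inputs: the package performs no fertility/mortality/
migration modelling of its own.

**Demand projection.** With base-year demand $Y_{a,g}$ aggregated from
patient-level records, the adjusted projection is
$$Y_{\text{target}} = \sum_a \sum_g W_{a,g}\, Y_{a,g},$$
and the *unadjusted* benchmark scales every stratum by the single all-age
both-sex ratio. The signed percentage gap between the two
(`misestimation()`) measures the cost of ignoring demographic structure.
The underlying assumption is constant age-gender-specific *rates*: each
stratum's per-capita propensity to generate ambulance calls stays at its
base-year level, so demand moves only with the stratum's population. Legal,
technological and epidemiological drivers are deliberately out of scope.

**Temperature effects.** Daily demand per stratum is related to daily mean
temperature by a convex quadratic $y = c + b_1 T + b_2 T^2$ fit with
ordinary least squares (`fit_quadratic()`). Because the projection operator
is linear, the same weights project the *equations*: all three coefficients
(and their confidence bounds) scale by $W_{a,g}$ (`project_equation()`), and
stratum equations sum coefficient-wise to a whole-population curve
(`combine_equations()`) whose vertex $T^* = -b_1 / (2 b_2)$ is the
temperature of minimum demand. OLS on counts (rather than a Poisson or
negative-binomial GLM) is a modelling choice that keeps this linearity
exact; the low explained variance typical of daily call counts is expected,
and the adjusted $R^2$ is used only to *compare* temperature sensitivity
across strata.

## Key parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| band scheme | 0–64, 65–74, 75–84, 85+ | years | resolution at which demand rates differ most; a coarser descriptive scheme (0–14, 15–34, 35–64, 65+) is available for profiles |
| `both_mode` | `sum_of_sex` | — | the literal double sum over sexes; `aggregate_weight` instead applies the both-sex weight to the both-sex cell (see below) |
| Grubbs `alpha` | 0.05 | — | conventional level for screening the base year against its neighbours |
| CI level | 0.95 | — | t-based intervals on the OLS coefficients, df $= n - 3$ |
| curve grid | 0–50 by 1 | °C | wide display range; extrapolated negative predictions are flagged, never clamped |

Weights, projections and coefficients are kept at full floating precision
internally; the export layer rounds (weights 2 dp, coefficients 2 dp,
demand to integers, percentages to integers) to match the conventional
table layouts.

## Two both-sex modes, and why both exist

With sex-specific weights, the both-sex projection can be formed two ways:
summing the projected sexes (`sum_of_sex`) or multiplying the both-sex base
cell by the both-sex weight (`aggregate_weight`). They disagree exactly when
male and female weights differ within a band — dramatically so for the 85+
band, where the female weight is several times the male one. Published
both-sex projection tables follow the aggregate convention, so the package
offers both: `sum_of_sex` is the default (it is the literal weighted double
sum and keeps both = male + female exactly), `aggregate_weight` reproduces
both-sex reference cells. For the same reason the packaged reference
demand table's both-sex cells slightly exceed male + female: source tables
count age-known/sex-missing records in the both-sex column only, whereas
the package's aggregation excludes records missing either field and reports
the exclusion count (`n_dropped`).

The "unadjusted" benchmark is defined as uniform scaling by the all-age
both-sex population ratio; back-computation from the reference projection
table confirms this is the convention behind its unadjusted columns (three
independent cells give the same implied ratio, ≈ 1.0405 for 2036).

## Numerical choices

- **Grubbs' test**: two-sided, $Z_i = |x_i - \bar x| / s$ with the
  sample (n−1) standard deviation, critical value
  $\frac{n-1}{\sqrt n}\sqrt{t^2/(n-2+t^2)}$ with $t$ the upper
  $\alpha/(2n)$ t-quantile on $n-2$ df (≈ 1.715 for $n = 5$,
  $\alpha = 0.05$). On the packaged yearly totals this reproduces the
  published Z statistics at printed precision.
- **Zero-demand days** are ordinary observations; dropping them would bias
  the fitted curves.
- **Ties and degenerate inputs**: fits require ≥ 3 distinct temperatures;
  a zero-variance sample yields all-zero Grubbs Z and "no outlier";
  weights are undefined (and an error) only for strata populated in the
  target but empty in the base.
- **Rounding propagation**: reference tables print weights and
  coefficients to 2 dp. Reproduction tests therefore allow, besides a 1%
  relative band, the propagated half-ulp of the printed inputs
  (0.005 × weight per projected coefficient; 0.005 × Σweights for
  combined sums). One visible artifact: the published combined base curve
  was summed *before* rounding, so its printed coefficients (−6.99, 0.13)
  differ in the last digit from the sum of the printed stratum
  coefficients (−6.98, 0.14), and only the former places the curve's
  vertex (26.9 °C) inside the 25–30 °C range.

## The synthetic-data generator

Restricted patient records cannot be shipped, so `eas_scenario()` defines a
generator whose defaults emulate a Taipei-like metropolis in 2015:

- **Pyramids**: eight strata (four bands × two sexes), 2.70 M residents,
  ~15% aged 65+; stratum counts grow geometrically with annual rates solved
  so the 36-year factors equal the published 2051 weighting factors (e.g.
  ×10.13 for women 85+).
- **Temperature**: $T(d) = 23 + 6\cos(2\pi (d - 196)/365.25) + N(0, 2^2)$
  °C — a subtropical cycle, warmest mid-July.
- **Records**: stratum-day counts are Poisson with mean
  $\max(0, c_0 + c_1 T + c_2 T^2) \times$ (population scaling), expanded to
  records with uniform within-band ages (85+ capped at 100), triage and
  trauma drawn from the published 2015 frequencies. Slopes and curvatures
  come from the published base-year equations; the constants are
  calibrated so each stratum's expected yearly volume under the noise-free
  cycle equals the published 2015 demand (2-dp rounding of near-zero
  curvatures would otherwise lose up to 15% of a stratum's volume).
  Records missing age or sex — 11.6% of the total, matching the published
  gap between all records and analyzable records — are generated *on top*
  of the stratum counts, since the rates describe analyzable records.

`ground_truth()` returns the closed-form weights, rates and expected yearly
volumes implied by a configuration, enabling parameter-recovery tests. All
randomness derives deterministically from the configured seed; identical
configurations produce byte-identical files.

**What passing tests do and do not show.** The generator reproduces the
*assumed* structure: geometric demographic drift, a stationary quadratic
temperature response, Poisson counts, independent days. Real ambulance data
have day-of-week and holiday effects, epidemic and heat-wave episodes,
overdispersion and spatial structure, none of which are simulated; recovery
on synthetic data validates the estimators and plumbing, not the model's
adequacy for any particular city. One concrete instance: with the published
2-dp coefficients as rates, Poisson noise does not guarantee that the
oldest stratum attains the largest adjusted $R^2$ (rounding flattens the
old-age curves' signal), so that ordering — observed in real data — is
tested on a scenario constructed with age-increasing temperature
sensitivity.

## Problem sizes

Tests run the full-size default scenario (~145,000 records/year) where the
margins themselves are under test, and a 20×-scaled-down variant for
structural and determinism checks; coefficient-recovery coverage uses 200
replicate stratum-years of 365 daily counts. The whole suite completes in
well under a minute.

## Limitations

- Point projections only: no uncertainty intervals on projected demand
  (official pyramids come without uncertainty, and the method's purpose is
  directional planning, not probabilistic forecasting).
- Constant per-capita stratum rates; no behavioural, policy or
  epidemiological drivers.
- Temperature model uses daily means only — no lags, humidity or heat
  indices — and extrapolated curves (e.g. to 50 °C) are descriptive, not
  predictions.
- Validation against realized future demand is impossible by construction;
  the test suite validates internal consistency and recovery of known
  synthetic truth.
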