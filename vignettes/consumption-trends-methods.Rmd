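---
title: "Methods: sugary-drink consumption trends by race and food environment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sugary-drink consumption trends by race and food environment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssbtrends)
```

# The problem

`ssbtrends` analyses repeated cross-sectional school surveys of adolescent
sugary-drink consumption. Each survey wave samples a fresh cohort of students
from the same set of middle schools; for five drink types (regular soda,
fruit drinks, sports drinks, energy drinks, flavored waters/teas) a student
reports a consumption-frequency category and a usual container type. The
package turns those categorical responses into two outcomes — daily-consumer
status and estimated daily calories — characterizes each school's attendance
zone as providing high or low exposure to unhealthy food retail, and
estimates wave-specific levels of both outcomes, overall and stratified by
race/ethnicity and by retail exposure, with school-level clustering handled
throughout.

Because district survey microdata and commercial establishment data of this
kind are not publicly distributable, the package also ships a calibrated
synthetic generator that emulates the study conditions end to end; every
statistical routine is exercised and validated against it.

# Calorie scoring

Daily calories from drink type $d$ are the product of three terms:

$$\mathrm{kcal}_d = f(\text{frequency category}) \times
  \mathrm{oz}(d, \text{container}) \times \mathrm{kcal/oz}(d, \text{container}),$$

summed over the five drink types. The frequency mapping $f$ is configuration,
not code. The shipped defaults follow standard food-frequency-questionnaire
conventions: `Never` = 0, sub-daily = 0.5, `1 time per day` = 1,
`2-4 times per day` = 3 (category midpoint), `5 or more times per day` = 5
(lower bound of the open-ended category). *Daily-consumer* status is
categorical, not numeric: a student is a daily consumer of a drink if and
only if the reported category is at least "1 time per day", so sub-daily
consumption contributes calories but never daily status.

Two policies handle partially missing responses. The default mirrors the
convention of coding non-reporters as consuming zero calories from that
beverage: a drink with a missing frequency, or a reported frequency but
missing container, contributes 0 kcal and `FALSE` to daily status. A strict
mode (`strict_missing = TRUE`) rejects such records instead.

The shipped catalog's ounce and kcal/oz entries are a clearly labelled
placeholder with conventional container sizes and typical product calorie
densities; analyses of real data should supply a catalog derived from an
authoritative beverage nutrition database (`read_catalog()`). All package
tests pin explicit fixture catalogs so no placeholder value is treated as
ground truth.

# Retail-exposure classification

Establishments are categorized from industry codes (fast-food restaurants,
convenience stores, gas stations with food, supermarkets/grocery; the code
table is replaceable configuration), assigned to attendance-zone polygons by
point-in-polygon containment (or supplied pre-assigned in geometry-free
mode), and tallied per zone. A zone's *unhealthy count* is fast food +
convenience + gas stations. The exposure rule is deliberately simple: a zone
is **high exposure** iff its unhealthy count is *strictly greater* than the
in-sample mean of that count; ties classify low. The threshold is computed on
the zone set entering the analysis — i.e. after any zone merging — and the
"merging zones that were already high stays high" scenario is verified as a
fixture test rather than assumed. Food-desert/food-swamp style metrics
(distance to supermarkets, retail ratios) are deliberately out of scope: the
emulated setting has uniformly good supermarket access, and the balance
diagnostics (`zone_balance_tests()`) check that enrollment and grocery counts
do not differ between exposure groups, supporting the unhealthy-count
criterion on its own.

`merge_zones()` operates on zone inventories: counts add, school ids union,
enrollment adds. No polygon union is materialized — merging happens after
establishments are assigned, so nothing downstream consumes merged geometry.

# Inference

For each outcome the package fits a random-intercept regression on survey
wave (categorical, baseline = first wave) — logistic for daily-consumer
status, linear for calories — optionally adjusted for race/ethnicity, with a
school random intercept:

$$g\!\left(E[y_{isw}]\right) = \alpha_w + \beta^{\top} x_{i} + u_s,
  \qquad u_s \sim N(0, \sigma^2_{\text{school}}).$$

Models are estimated by maximum likelihood via `lme4` (adaptive
Gauss–Hermite quadrature with 25 points for samples up to 500 rows, Laplace
beyond that, where it is accurate and much faster; linear models use ML, not
REML).

**Reported scale.** Prevalence estimates are population-averaged: predicted
probabilities integrate the school random intercept out by quadrature and are
averaged over the analysis sample's covariate distribution, yielding a
percent-of-students scale. A `conditional = TRUE` flag reports the
conditional-on-zero-random-effect scale instead. Calorie estimates are
model-based wave means at the sample's covariate composition.

**Uncertainty.** Standard errors are cluster-robust at the school level — a
sandwich built from per-school scores of the *marginal* likelihood (schools
are independent under the model, so the marginal log-likelihood is a sum of
per-school terms; scores and the Hessian are obtained by numerical
differentiation at the fitted parameters, with a $G/(G-1)$ small-sample
factor). The logistic per-school likelihood uses adaptive Gauss–Hermite
quadrature centered on each school's posterior mode; the linear one is the
closed-form compound-symmetric Gaussian. With random intercepts *and* robust
errors this is belt-and-braces, which is intentional. Confidence intervals
are Wald on the link scale, transformed to the reporting scale, and — like
the contrast tests — use $t$ quantiles with $G-1$ degrees of freedom, the
standard small-sample practice for cluster-robust inference (null
simulations with normal quantiles showed mild family-wise error inflation at
$G \approx 19$ clusters; the $t_{G-1}$ reference restores nominal control).

**Baseline contrasts.** Each post-baseline wave is compared with baseline by
a two-sided Wald test on its wave coefficient; p-values are
Bonferroni-corrected within one table's family (the $m$ post-baseline waves,
$m = 3$ after wave exclusion — not across tables), and flagged at
$\alpha = 0.01$ by default.

**Stratification.** Full-sample models adjust for race/ethnicity;
race-stratified models are unadjusted; exposure-stratified models keep the
race adjustment. Students with missing race are dropped from adjusted models
(and logged), retained in unadjusted summaries. Empty strata are reported
and skipped rather than failing the run.

**Wave exclusion.** Waves whose survey response rate falls below
`min_rate` (default 0.5) are removed before analysis and logged; the default
synthetic calibration contains one such wave (30% response) precisely so the
filter has something to do in end-to-end runs.

Auxiliary tests mirror the rest of the design: a Welch two-sample $t$-test of
the daily-consumer share between exposure groups pooled over waves, a Pearson
chi-square (no continuity correction) of race by exposure group, and paired
per-school $t$-tests comparing sample race shares with the full-population
shares.

# The synthetic generator

`default_study_config()` encodes the emulated study conditions: five waves
(response rates 91/65/30/90/81%; the 30% wave exists to be excluded), about
13,130 analysed students, 19 schools each with its own attendance zone, a
five-group race mix (county shares, normalized), overall daily-consumption
prevalence declining 49.4% → 36.9%, final-wave race-specific prevalences,
mean calories declining 220 → 158 kcal/day, race-specific probabilities of
living in a high-exposure zone (21.6–33.2%), a pooled exposure prevalence
gap of ~7.1 percentage points that widens over time, and zone establishment
means (fast food 14.2 vs 7.3; convenience+gas 3.8 vs 2.4). Interior-wave
levels are not published anywhere we can cite, so the defaults interpolate a
smooth decline; between-school SDs (0.3 logits for prevalence, 30 kcal for
calories) are likewise unpublished defaults, chosen as plausible for school
populations of this size, and configurable.

Design choices worth knowing about:

* **Calibration solves the cell table, not the margins.** Race offsets are
  held constant across waves on the logit scale (anchored at the final-wave
  race-specific levels); per wave, an intercept and an exposure effect are
  solved numerically so the mix-weighted overall prevalence and the high–low
  gap hit their targets exactly. Calorie cell means interpolate race
  trajectories and are rescaled per wave to the overall target. Note one
  unavoidable tension: the emulated study's printed final-wave stratified
  prevalences (45.3/35.6%) average to 38.0%, not to its printed overall
  36.9% — different models produced them. The calibration keeps the overall
  at 36.9% with a final-wave gap of 9.7 pp, implying a high-exposure
  final-wave level near 44.2%.
* **Consumption is generated at the category level.** Students draw
  frequency and container *categories*, never a kcal number, so the scoring
  module is genuinely exercised. Given a cell's daily-consumer share, a
  single intensity parameter $\theta$ governs sub-daily reporting
  probabilities per drink ($1 - e^{-\theta W_d}$, $W_d$ = drink popularity)
  and the escalation of a daily consumer's primary drink through the daily
  frequency categories (a Binomial(2, $\theta/(1+\theta)$) mixture over
  1/2–4/5+ per day). The expected scored kcal is available in closed form,
  and $\theta$ is solved per school-cell by root finding against the active
  catalog — so calibration holds under whatever catalog is supplied.
* **Balanced sampling is the default.** In `sampling = "balanced"` mode,
  realized daily-consumer counts and categorical draws per school-cell are
  the randomized rounding of their expectations (expectations unchanged,
  sampling noise reduced to rounding level) — the way calibrated synthetic
  populations are usually constructed, so the generated cohort reproduces
  the configured margins rather than a noisy draw around them. The important
  caveat: such a cohort carries *less* sampling variance than a real survey,
  so standard errors estimated from it understate real-survey uncertainty.
  Studies of the estimators themselves (error calibration, power) must use
  `sampling = "bernoulli"`, as the package's own family-wise-error tests do.
* **Exposure is the realized classification.** The generator classifies its
  own city with `classify_zones()` and allocates students by race-specific
  probabilities into the *realized* high/low groups, so generator truth and
  downstream classification can never disagree. Zone establishment counts
  scatter with bounded relative dispersion (±15%, rounded) around the
  regime means rather than Poisson: with the configured means (≈18 vs ≈9.7
  unhealthy establishments), Poisson dispersion would push roughly a quarter
  of low-regime zones across the in-sample-mean threshold, contradicting the
  emulated setting's stable zone coding and ~24.6% high-exposure student
  share, and the resulting mismatch between the school-count share and
  student share of high zones would bias the mixed-model wave estimates
  (school random effects absorb the zone-level exposure effect but are
  assumed mean-zero).
* **School effects are centered** (sum to zero within each exposure group),
  so a finite draw of 19 school intercepts does not shift the cohort's
  realized margins away from the calibration.
* No within-student longitudinal correlation (the design is repeated
  cross-sections) and no gender effects are modeled.

What passing the recovery tests shows — and does not show: the pipeline run
on generator output recovers the configured quantities at the study's sample
sizes, which validates the scoring, classification, and estimation machinery
end to end. It does not validate the generator against real microdata, which
are unavailable; recovery is always measured against generator truth.

# Numerical choices

* Gauss–Hermite rules use 15 nodes; the logistic marginal likelihood adapts
  node location/scale per school (posterior mode and curvature, Newton
  iterations), which is essential once schools have hundreds of students and
  the integrand is much narrower than the random-effect prior.
* Numerical scores/Hessians use central differences with relative step
  `1e-5`; degenerate variance components (singular fits, single school) are
  dropped from the parameter vector rather than differentiated at a log
  boundary.
* Separation guard: any fitted |coefficient| > 15 on the logit scale aborts
  with the offending term named.
* Root finding (`uniroot`) tolerances are 1e-7–1e-10; the intensity solver
  clamps at its bracket ends (a cell whose target is below the minimum
  achievable kcal generates at the minimum).
* Boundary points in point-in-polygon assignment follow the containment test
  of `mgcv::in.out()`; establishments are generated in zone interiors, and
  the documented tie-break (first containing zone in zone-id order) matters
  only for constructed inputs.
* The balanced-mode randomized rounding selects the extra units with
  probability proportional to fractional parts; this is exactly unbiased for
  the rounding of a single probability and very nearly so for multinomial
  cell counts.

# Problem sizes in the shipped tests

The test suite keeps fixtures small by design: unit fixtures are 24–250
rows; the shared pipeline cohort is 500 students/wave across 6 schools; the
family-wise-error simulation runs 200 replicates of 1,520 students across 19
schools; and the calibrated-recovery checks run the full ~14,300-student
default cohort once and reuse it across assertions. The acceptance script
regenerates the full cohort and refits all headline models in under a minute
on one core.

# Limitations

* The placeholder catalog's calorie densities are plausible but not
  authoritative; absolute kcal levels from it should not be quoted for real
  populations.
* The retail snapshot is a single year applied to all waves, mirroring the
  emulated study's own limitation.
* Cluster-robust inference with ~19 clusters is approximate even with
  $t_{G-1}$ quantiles; simulations show nominal family-wise error control at
  the shipped settings, but very small numbers of schools (say, under 10)
  would warrant wild-cluster bootstrap methods the package does not
  implement.
* The generator's interior-wave levels, between-school variances, and
  within-cell kcal dispersion are assumptions; all recovery tests compare to
  generator truth, not to unavailable microdata.
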