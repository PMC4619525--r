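---
title: "Evaluating hospital sampling strategies by simulation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating hospital sampling strategies by simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hospsample)
```

## What the package computes

`hospsample` evaluates five stratified strategies for selecting a small
sample of hospitals from a finite population, judging each by how well a
Poisson regression fitted on the sample predicts blood-product use for
*every* hospital in the population. Two percentages of the true population
total summarize each replicate: the hospital-level error (summed absolute
prediction errors) and the national-level error (absolute deviation of the
summed prediction). By the triangle inequality the national error can never
exceed the hospital-level error; the gap measures how much over- and
under-predictions cancel in the national total.

The workflow is: generate or read a population → draw selections with a
strategy → fit one Poisson model per product on the selection → predict all
hospitals → compute both errors → replicate and summarize.

## The prediction model and its assumptions

For each product (red cells `rbc`, plasma `ffp`, platelets `plt`) the model
is a log-link Poisson regression on hospital type (indicator terms,
reference level `general`) and bed count:

$$\log \mu_h = \beta_0 + \beta_{\text{acad}}\,[t_h = \text{acad}]
 + \beta_{\text{teach}}\,[t_h = \text{teach}] + \beta_b\, b_h .$$

One joint model per product is fitted rather than three per-stratum models:
every scenario samples all three strata, so the type indicators are always
estimable, while 6–18 observations cannot support interactions. A per-type
bed-slope option (`per_type_slopes = TRUE`) is exposed for sensitivity
analysis on the larger scenario.

Fitting uses iteratively reweighted least squares (base R's `glm.fit`),
declaring convergence when the relative deviance change drops below `1e-8`,
capped at 100 iterations. For any converged fit with an intercept the score
equations force the in-sample fitted sum to equal the observed sum — the
test suite verifies this identity, and verifies the coefficients against an
independent quasi-Newton maximizer of the explicit log-likelihood. No
overdispersion correction is applied in fitting: the error metrics use
point predictions only, and the quasi-Poisson variance inflation would not
change them. Replicates whose fit fails (a rank-deficient design or
non-convergence) are counted and excluded from summaries rather than
silently included, which would corrupt the centiles; failure counts are
reported in every summary.

## The sampling strategies

All strategies are stratified by hospital type with a 1:1:1 ratio; the
scenarios are A = 4, B = 6 and C = 2 hospitals per stratum. Deterministic
rules break all ties (equal beds, equal RBC counts) by ascending hospital
id — reproducibility over arbitrariness.

* **`larg`** — per stratum, the `n` hospitals with the most beds.
* **`maxvar`** — per stratum, `ceiling(n/2)` hospitals with the highest and
  `floor(n/2)` with the lowest RBC count, keyed on RBC only. The extra seat
  for odd `n` goes to the high end (high-use hospitals carry more counts and
  hence more likelihood information); `high_end_extra = FALSE` flips this.
* **`rand`** — simple random sampling without replacement within stratum;
  inclusion probability is exactly `n/N` per stratum.
* **`regvar`** — the regions occupied by the stratum are randomly permuted
  and seats filled round-robin, one uniformly drawn hospital per region per
  pass; the number of regions represented is always
  `min(n, occupied regions)`.
* **`2reg`** — all academic centres inside a pair of regions (two, or three
  when the pair includes the dual-academic region), and for the other strata
  an even split of `n` across the pair, the odd seat assigned to a random
  member. A region that cannot fill its share passes the seats to the other
  region; if the pair jointly holds fewer than `n`, everything is taken and
  the shortfall is recorded on the selection. The even split is a design
  choice: the selection rule is inherently per-region, and an even split is
  the least-assumption reading of taking "a large part" of two regions.
  Replicated runs draw the pair uniformly from all `choose(7, 2) = 21`
  pairs; `run_pairs()` instead reports each pair separately, which is the
  mode to use when inspecting differences between specific region
  combinations.

Infeasible scenarios (a stratum smaller than `n`) fail loudly naming the
stratum, rather than silently truncating — except the within-pair `2reg`
fallback, which is part of the strategy's definition.

## Monte Carlo design

`run_replicates()` simulates one strategy; `run_experiment()` crosses
scenarios with strategies. Deterministic strategies are evaluated once and
replicated logically. Random strategies run in `n_batches` independent
batches of `n_reps` replicates (defaults 10 × 1000); the per-batch summary
statistics are averaged for the report and the dispersion of batch medians
is reported alongside. Averaging batch summaries and pooling all replicates
are both defensible; the package reports the batch average and keeps the
tidy per-replicate table so the pooled statistic can be recomputed, and the
test suite checks the two agree within the batch standard error.

Every random stream is derived by stably hashing the master seed with the
strategy, scenario and batch labels (`derive_seed()`), so adding or removing
one strategy never perturbs another's draws, and any single batch can be
reproduced in isolation.

Summaries are the median, mean, and 2.5th/97.5th percentiles ("95%
centiles") computed by linear interpolation between order statistics.
Head-to-head tables report the percentage of random replicates with an
error *strictly* below the purposive strategy's error; ties count as not
outperforming, which is conservative toward the purposive strategy. Errors
are carried at full precision and rounded to whole percent only in the
printed table.

By default both error metrics are computed over all hospitals in the
population, sampled ones included, since the prediction target is the full
national landscape; `holdout_only = TRUE` restricts them to non-sampled
hospitals for the strict out-of-sample reading.

## The synthetic-population generator

Real hospital-level blood-use data are confidential, so the package ships a
generator whose defaults emulate the documented structure of the Dutch
hospital landscape in 2013: 89 hospitals (8 academic, 28 teaching, 53
general) in 7 organizational regions, academic centres spread one per region
except two in one region, and annual product counts that grow exponentially
with bed count within each stratum.

Counts are drawn as

$$y_{hp} \sim \text{Poisson}\!\big(e^{\alpha_{p,t_h} + s_p b_h}\, L_h\,
E_{hp}\big),$$

where $L_h$ is a mean-one log-normal effect shared by all products of a
hospital (`latent_sd`) and $E_{hp}$ an independent mean-one log-normal
effect per product (`noise_sd`, a scalar or per-product vector). The shared
effect raises the rank correlation between products; the independent effect
lowers it. Both are needed: with realistic count magnitudes the Poisson
noise is negligible, so without $E_{hp}$ the three products would be almost
perfectly rank-correlated through their shared dependence on beds and type.

Default parameters (all overridable in `generator_config()` or a YAML file;
see `inst/extdata/generator-config-example.yaml`):

* **bed ranges** — academic 700–1350, teaching 400–900, general 150–600
  beds, uniform integers: size-separable strata with partial overlap.
* **slopes** `s_p` — 0.0025 (`rbc`), 0.0028 (`ffp`), 0.0032 (`plt`) per
  bed on the log scale, with intercepts set so that mid-range hospitals
  issue realistic annual counts (a mid-size general hospital ≈ 3,500 RBC
  units, a mid-size academic centre ≈ 20,000). The steepest slope is given
  to platelets, whose use concentrates in the largest hospitals. These
  values make the exponential beds–use association clearly visible within
  each stratum, which is the premise of the whole prediction approach.
* **`latent_sd` = 0.12, `noise_sd` = (rbc 0.08, ffp 0.33, plt 0.30)** —
  calibrated by grid search so that repeatedly generated populations show
  mean Spearman correlations with RBC of ≈ .88 (FFP) and ≈ .92 (PLT), the
  two distributional facts documented for the real population. The noise is
  smallest for red cells, whose use tracks overall hospital activity, and
  larger for plasma and platelets, whose use varies more between hospitals
  (case mix, wastage, short shelf life). Under these defaults a stratified
  random sample of 12 hospitals leaves a median hospital-level RBC error
  around 12–13%, i.e. the generator operates in a realistic error regime.

### What the generator does *not* emulate

The generating mean structure is exactly the model family that the
inference step fits. Real populations deviate systematically from any
fitted family — curvature in the beds relationship, region effects,
hospital-role effects beyond the three types. This matters for
interpretation: model-based inference from a *correctly specified* model is
robust to sample composition, so on these synthetic populations the random
strategies predict essentially as well as purposive maximum-variation
sampling, and `maxvar`'s selection of hospitals that are extreme partly
through their own idiosyncratic effects slightly biases its fit. The
acceptance checks quantify exactly this: across repeated default
populations, the `maxvar` hospital-level RBC error typically falls at or
slightly above the `rand` median. A decisive advantage of extreme-value
sampling — avoiding extrapolation — can only materialize when reality and
model disagree systematically. Passing simulations here therefore validate
the machinery (selection rules, estimation, error accounting, reproducible
replication), not a claim that any particular strategy is best on real
data; for a real design decision the generator should be replaced or
augmented with the actual proxy data via `read_population()`.

Also not modelled: the three excluded specialized centres, the hospital
excluded for missing data, geographic coordinates (regions are labels, not
shapes), and any temporal structure.

## Numerical and degenerate-input conventions

* IRLS tolerance `1e-8` on the relative deviance change, 100-iteration cap;
  initialization is `glm.fit`'s standard starting point.
* Centiles interpolate linearly between order statistics (the `type = 7`
  convention); a single value yields itself for every statistic.
* Zero population totals make the error metrics undefined and raise an
  error rather than returning `NaN`.
* An empty population, duplicate ids, unknown type or region labels, and
  negative or non-integer counts are rejected at construction with messages
  naming the offending row and column.
* A configuration with fewer than two academic centres degrades the
  dual-academic-region rule and warns.
* Scenario percentages of the population (13%, 20%, 7%) are reported with
  conventional rounding of `100 n / N`.

## Problem sizes used by the test suite

The suite exercises the study-scale configuration directly: the full
three-scenario, five-strategy experiment at 10 × 1000 replicates; parameter
recovery on 200 populations at ten times the stratum sizes (890 hospitals)
with hospital effects switched off; 10,000-replicate inclusion-frequency
checks for random sampling; 100 generated populations for the correlation
calibration; and 20 populations for the across-population strategy ranking.
These sizes keep every Monte Carlo tolerance (3 standard errors unless
stated otherwise) meaningful while the whole suite runs in a few minutes.

## Known limitations

* The ranking of strategies on synthetic data should not be read as advice
  for real data collection (see above); the package's contribution is the
  evaluation machinery.
* Only point predictions are produced; prediction intervals would require a
  variance model the error metrics do not use.
* The amended maximum-variation idea of spacing hospitals evenly across the
  outcome range, and richer predictor sets (cardiac surgery, admission
  diagnoses), are out of scope.
* Costs, feasibility and cooperation of the selected hospitals — often the
  deciding factors in practice — are not modelled.
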