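---
title: "Methods: estimating effective cataract surgical coverage from cluster-sample surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating effective cataract surgical coverage from cluster-sample surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eyecover)
```

## The indicators and their assumptions

Cataract surgical coverage (CSC) is the proportion of people who have been
operated for cataract among all who were operated or still need surgery;
effective CSC (eCSC) keeps the same denominator but restricts the
numerator to operated people with a good presenting visual outcome. Both
are person-level indicators computed from a cross-sectional survey of
adults aged 50 and over — the age group carrying nearly all
cataract-related vision impairment — with per-eye lens status, presenting
and best-corrected acuity, and principal cause of impairment.

The acuity data are the 5-level ordinal categories used by RAAB-style
field surveys, and every threshold in the pipeline is a cut-point of that
scale: an unoperated cataract eye *needs surgery* when its best-corrected
acuity is strictly worse than the surgical threshold, and an operated
person has a *good outcome* when the presenting acuity of the better
operated eye is at or better than the outcome threshold. Using presenting
(rather than best-corrected) acuity on the outcome side reflects the
patient's lived visual experience, including residual refractive error.
Both thresholds default to 6/18; 6/12 outcome and all four surgical cuts
(<3/60, <6/60, <6/18, <6/12) are available, and `threshold_matrix()`
evaluates the full grid. Because the scale is strictly ordered, no
comparison can tie, and classification is a pure function of the row.

### Who counts, and two deliberately exposed rule variants

Two readings of the person-level inclusion rules are defensible, so both
are implemented behind `indicator_config()` and every output row carries a
canonical descriptor of the configuration used:

* `unilateral_rule = "all_operated"` (default): every person with at
  least one operated eye is in the CSC numerator. This matches the plain
  definition of "people with operated cataract".
* `"fellow_impaired_only"`: a person with exactly one operated eye counts
  only if the unoperated fellow eye is itself below the surgical
  threshold — i.e. unilateral surgery on someone whose other eye sees
  well is not counted as met need. Persons whose fellow eye cannot be
  graded (no view, missing acuity) are conservatively excluded from the
  numerator and tallied.

Similarly, an operable eye by default requires cataract to be the recorded
principal cause of impairment, so vision loss from other disease does not
create apparent unmet surgical need; `require_cataract_cause = FALSE`
gives the looser reading (any cataract lens below the cut).

### Missing data

Field data contain gaps, and the sources are silent on their handling, so
the package takes an explicit, auditable position: a participant with
missing lens status in both eyes is unclassifiable and excluded from every
group; an operated person whose presenting acuity is missing in all
operated eyes stays in the CSC numerator and denominator but is excluded
from the eCSC numerator; both exclusions are counted and reported by
`survey_counts()`. A best-corrected acuity worse than the presenting
acuity in the same eye is logged as a soft warning, not rejected — it
occurs in real data.

## Estimation

### Post-stratification

Estimates are standardised to the age-sex structure of the survey-area
population: census counts in the 8 strata (two sexes × 50–59, 60–69,
70–79, ≥80, left-closed bands) divided by the numbers examined give
stratum weights `w_s = N_s / n_s`, applied to each participant before any
summation. The weight direction deserves a note: adjustment factors for
this design are sometimes worded the other way around, as examined over
population, but that multiplier would weight strata by their sampling
fraction — the opposite of standardising to the population's age
structure. The package uses population-over-examined, which makes the adjusted estimate exactly
the crude estimate whenever sampling fractions are uniform (a tested
identity) and leaves estimates invariant to rescaling all census counts.
Sex-restricted estimates use only that sex's strata, i.e. they are
age-adjusted only. A stratum with population but no examined participants
has no weight; by default its census count is collapsed into the adjacent
age band of the same sex (towards the younger band, except 50–59 which
folds upward), conserving the per-sex total, with a logged message —
or `empty_stratum = "error"` for strict runs.

### Cluster-adjusted standard errors

RAAB surveys are two-stage cluster samples, so binomial standard errors
would be too small. The package uses the classical ratio-estimator
cluster variance: with per-cluster weighted pairs `(y_i, x_i)` and
`r = Σy/Σx`,

`SE = 100 · sqrt( c/(c−1) · Σ (y_i − r x_i)² ) / Σ x_i`.

The constant was cross-checked two ways: the `(2,10),(4,10),(6,10)`
hand example (SE 11.55 points) and a 2,000-replicate cluster bootstrap on
a 50-cluster synthetic survey, which agrees with the formula to about 2%
(the test asserts 15%). Weights are applied at the participant level
*before* forming cluster totals, so the SE reflects weighting and
clustering jointly. Clusters with nobody in the denominator contribute
`(0, 0)` pairs and remain in `c`: the number of clusters is a property of
the design, not of the outcome. The 95% CI is the untransformed normal
approximation `value ± 1.96·SE`, clipped to `[0, 100]`; no logit or
arcsine transform is applied because the estimator is used on coverages
far from the boundary and the clipping handles the rest. A zero weighted
denominator yields an explicitly undefined estimate (`NA`), never 0 or
100. Fewer than two clusters is a hard design error. Internally
everything is double precision; the 1-decimal rounding of
`format_estimate()` is presentation only.

No finite-population correction is applied: real surveys of this kind
sample a tiny fraction of their source population, and the synthetic
validation populations are built large (hundreds of clusters) to respect
that assumption.

## Country estimates, pooling, grouped summaries

Where a country has several surveys, `select_country_surveys()` applies a
decision tree favouring recency and representativeness: any nationally
representative estimate (single national survey, or a survey series
declared national in its metadata — declared, never inferred) beats all
subnational ones, newest first; otherwise the newest subnational survey is
pooled by fixed-effect inverse variance with every subnational survey
completed within 3 years before it, boundary inclusive (a 2019 anchor
pools 2016, not 2015). Ties on year break by larger sample, then by
survey id — a deterministic, metadata-only rule, so adding an older survey
can never alter a selection made from newer ones. Fixed-effect weighting
(`1/se²`) is used here because within-country subnational estimates are
being averaged into one number, not modelled as a distribution;
zero-variance inputs are rejected with a diagnostic rather than absorbing
infinite weight. Grouped summaries (by region or income labels, which are
free-text metadata, not computed lookups) report median, IQR and range
with type-7 linear-interpolation quantiles — R's default, stated here
because the choice is not neutral at these small group sizes — plus the
survey count and year span.

## Sex-disparity meta-analysis

Per survey, `sex_effect()` computes age-adjusted male and female coverage
and derives the risk difference on the percent scale
(`SE = sqrt(se_M² + se_F²)`, treating the sexes as independent strata of
the same design) and the risk ratio with its delta-method log-scale SE.
`pool_random_effects()` re-implements DerSimonian–Laird pooling:
`Q = Σu(e−ē)²`, `τ² = max(0, (Q−(k−1))/(Σu − Σu²/Σu))`, random-effects
weights `1/(se²+τ²)`. With `τ² = 0` it reduces exactly to fixed-effect
pooling (tested). Risk ratios are pooled on the log scale and
exponentiated, standard practice for ratio measures; risk differences are
pooled in percentage points. The implementation is validated against an
independent reference implementation (metafor) and a hand-worked
two-study example. Surveys where a sex has a zero denominator are
excluded with a diagnostic; no continuity correction is applied for zero
numerators — such surveys are excluded from RR pooling rather than
adjusted.

## The synthetic generator: what it does and does not emulate

`raab_scenario()` describes a population of adults 50+ and a two-stage
sample of it. The person model is the smallest one that exercises every
classification branch: per-stratum probabilities of bilateral or
unilateral cataract need, a logistic access model with a male log-odds
offset, an age gradient and a cluster-level normal random effect (its
variance set from the latent-logistic intra-cluster correlation
`σ² = ρπ²/3/(1−ρ)`), configurable bilateral-surgery and aphakia shares,
an outcome distribution over acuity categories for operated eyes, a
severity distribution for unoperated cataract eyes, and a non-cataract
impairment branch. Persons are independent given their cluster; there is
no disease progression, no measurement error beyond the categorical
draws, and no correlation between a person's two eyes beyond the shared
need state — all deliberate omissions, so passing tests demonstrate
estimator correctness under the stated design, not realism of any
particular epidemiological setting.

Defaults mirror the scale of real surveys: 50 clusters × 60 participants
(≈3,000, close to the median size of published RAABs), a 48,000-person
source population in 120 clusters, cataract need rising from 5% to 35%
across the age bands, 50% access with a 0.3 male log-odds advantage
(producing a male–female eCSC gap in the few-points range seen in
practice), ρ = 0.05, and 75% good outcomes. Real cluster sizes and
intra-cluster correlations are not published; these are plausible
placeholders, and every one is a constructor argument.

`generate_population()` consumes the root seed; `sample_survey()` takes
its own (the convenience wrapper uses `seed` and `seed + 1`), so the
population and the sampling stage are independently reproducible. Ground
truth is never a formula: `roster_truth()` classifies every person in the
roster and reads off census CSC, eCSC, quality gap and sex effects, which
is what the estimator is tested against.

## Validation problem sizes

The test suite validates, among other properties: the subset chain
eCSC ⊆ CSC ⊆ denominator on 1,000 randomized participants across all
eight threshold configurations; exact recovery of census truth when the
estimator runs on a full 100,000-person roster (all weights 1);
agreement of the cluster SE with a 2,000-replicate cluster bootstrap;
95% CI coverage within 93–97% over 500 simulated surveys of 3,000
participants drawn from a 600,000-person population calibrated to a
census eCSC near 40% (Bennett-style SEs are conservative, so coverage
sits at or above the nominal level); and recovery of a configured
3-point male–female risk difference, with 1-point between-survey
heterogeneity, by DL pooling over 50 simulated surveys. These sizes are
the package's chosen validation conditions and are fixed in the tests.

## Known limitations

* Eye-level coverage indicators and refractive-error coverage are out of
  scope; the package is person-level by construction.
* The CI is a symmetric normal approximation; for coverages near 0 or
  100 with few clusters it can clip, and an interval transform might be
  preferable.
* Region and income groupings are metadata labels; the package performs
  no geographic or income-classification lookups.
* The generator's minimality means it cannot calibrate to a specific
  country's joint distribution of age, access and outcomes; it is a
  validation instrument, not a forecasting model.
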