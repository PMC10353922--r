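---
title: "Methods: quantifying sex-specific floral visitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying sex-specific floral visitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

sexforage analyses long-term floral-visitation records of a flower-visiting
insect whose males and females differ in flight phenology — the motivating
system is a protandrous grassland butterfly in which males emerge about two
weeks before females — and asks three questions: do the sexes visit a
different *diversity* of nectar plants, do they differ in the *relative
composition* of plants visited, and do those differences survive once the
analysis is restricted to the part of each season when both sexes are
actually flying? A companion module contrasts nectar chemistry between the
plant species each sex over-visits.

```{r}
library(sexforage)
```

## Data model

The universal input is a long-format table of nectaring observations —
`year`, `ordinal_day` (January 1 = day 1), `sex` (F/M), `plant_species`,
and an optional `count` defaulting to 1. Each row is an individual feeding
event; duplicated rows are legitimate (two butterflies on the same plant on
the same survey day) and are never deduplicated. Species labels are
whitespace-squished and case-unified because two decades of hand-entered
field data inevitably drift in spelling. Nectar data are long-format
`(species, sample_id, compound, concentration)` rows, one biological
replicate being one plant individual.

## Resolving genus-level thistle records

Some records are identified only as "Cirsium spp." although two congeners
with nearly disjoint flowering seasons occur at the site. Because the
observation date separates the two species almost perfectly, we resolve
these records with a one-dimensional maximum-margin threshold on ordinal
day, trained on the unambiguous records pooled across years. With a single
feature, any linear support-vector rule reduces to a day threshold, so this
choice keeps the stage fully auditable: the fitted object exposes the
boundary, the per-class training summary, and a deterministic tie rule
(records exactly on the boundary go to the class with more training weight
within ±7 days). For perfectly separable classes the boundary is the
midpoint of the closest cross-class pair; for overlapping classes it
minimizes count-weighted training error first and maximizes the margin
among minimizers.

## Phenological overlap windows

Weekly sex ratios use fixed 7-day bins anchored at ordinal day 1 (days 1–7
= week 1). Calendar/ISO weeks were rejected deliberately: they shift with
locale and year and would make windows irreproducible across systems.

The overlap window for a year runs from the first week in which females
comprise at least 25% of observations through the last week in which they
comprise at most 75%. Two readings of the verbal rule are defensible —
"last mixed week" versus "the week females first exceed 75% ends the
window" — and they differ when the female share dips back below 75% late in
a season. We implement the first as the default (`rule = "caption"`) and
expose the second (`rule = "methods"`); both are tested.

A window is *excluded* (exclusion is a value on the window, not an error)
when no qualifying weeks exist or when fewer than `min_days = 4` distinct
observation days fall inside it: a window narrowed to a handful of survey
days cannot support a within-year comparison of the sexes. The default of 4
excludes windows spanning 1–3 observation days while retaining typical
multi-week seasons. Window bounds are inclusive at day resolution on both
ends.

Median foraging dates per sex-year use the count-weighted lower median, so
the statistic is always an observed integer day; the per-year dissimilarity
is then regressed (OLS) on the absolute female–male median-date gap to ask
how much interannual variation in foraging divergence phenology explains.

## Diversity: Hill numbers and the paired mixed model

For each sex-year assemblage we report species richness and the effective
species number `exp(H)`, with `H` the Shannon entropy on natural logs
(`0 log 0 = 0`). The effective species number is the Hill number of order
1 — the number of *equally visited* species giving the same entropy — so a
sex difference reads directly in "species' worth" of diversity rather than
in nonlinear entropy units. The natural-log base is fixed; the base cancels
in `exp(H)` only when the same base is used throughout.

Sexes are compared with the linear mixed model `metric ~ sex + (1 | year)`
fitted by REML, the year random intercept absorbing the within-year pairing
of the two sex values. We report the female-minus-male effect with
Satterthwaite degrees of freedom, which we consider the honest df
convention for this design rather than forcing any particular integer. A
singular fit (between-year variance estimated at exactly zero) falls back
to a paired t-test on the per-year differences, with a message. No
rarefaction is applied: each sex-year uses all of its records, and per-year
sign comparisons are reported only for years in which both sexes have
records.

Because interannual autocorrelation would violate the model's independence
assumption, `residual_time_diagnostics()` reports the residual ACF at lags
1..min(15, n−2) and the Durbin–Watson statistic computed from its
definition, `DW = Σ(e_t − e_{t−1})² / Σe_t²`.

## Dissimilarity and the marginal-preserving null

Composition differences use the abundance-based Morisita–Horn
dissimilarity

$$d_{mh} = 1 - \frac{2\sum_i x_i y_i}
  {\left(\sum_i x_i^2/X^2 + \sum_i y_i^2/Y^2\right) XY},$$

with `x`, `y` the female and male visit-count vectors and `X`, `Y` their
totals; 0 means identical relative composition, 1 means no shared species.
The Horn (information-overlap) variant is deliberately *not* used; this is
the probability-of-drawing form, symmetric and invariant to proportional
scaling of either assemblage. Floating-point rounding is clamped to
[0, 1].

Each year's observed value is compared with `n_reps = 1000` random tables
holding both margins fixed — the same number of female and male visits and
the same per-plant totals, with sex–plant links randomized. The sampler is
Patefield's algorithm: each row is filled cell by cell from the conditional
hypergeometric distribution given the remaining margins, which draws
exactly from the permutation (generalized hypergeometric) null. The test
suite verifies it against exhaustive enumeration of label shuffles on
small margins and against an independent label-shuffle sampler.

The null band is the central 95% *percentile* interval of the null values
(linear-interpolation quantiles, R type 7), not a normal approximation: the
null distribution of `d_mh` is often skewed and discrete on small margins.
A mean ± 1.96 SD band is available via `ci_type = "sd"`. Observed values
strictly above the band are classified "above" (more dissimilar than
random re-pairing allows), strictly below as "below", otherwise "within".
A year in which only one plant species was visited has a degenerate null
(all values 0) and is classified "within"; a year missing one sex entirely
is marked non-computable rather than silently dropped.

Reproducibility: a master seed spawns one pre-drawn seed per (sorted)
year, so per-year results are bit-for-bit reproducible and independent of
the order in which years are processed.

## Sex–plant association

Pooled over years (individual years rarely satisfy expected-count
guidance), a 2 × S Pearson chi-squared test of independence without
continuity correction identifies the species driving sex differences.
Species are labeled from the female-row Pearson residual
`(O − E)/√E`: above +2 female-associated, below −2 male-associated,
otherwise neutral. The threshold 2 approximates a standard-normal
criterion; it is exposed as `residual_threshold` because the labeling, not
the omnibus test, feeds the nectar contrast. Cells with expected counts
below 5 trigger a warning listing the cells but never suppress the test.

## Nectar chemistry contrasts

Outlier screening removes a concentration lying more than `k = 4` SD from
the mean of the *other* members of its species × compound group
(leave-one-out). The leave-one-out form is a mathematical necessity, not a
preference: with the candidate included, the largest attainable deviation
in a group of n values is `(n−1)/√n` SD — about 3.3 at n = 13 — so a 4-SD
rule computed with the candidate included could never remove anything.
Groups with fewer than 3 values are left unscreened.

The group contrast treats each species as having its own mean *and its own
residual variance*, because variance heterogeneity among species is the
rule for nectar metabolites. The planned contrast is the mean of
female-associated species means minus the mean of male-associated species
means, with variance `Σ c_i² s_i²/n_i`, `F = (L/SE)²` on 1 numerator df,
and Welch–Satterthwaite denominator df. The pooled residual df
`Σ(n_i − 1)` is reported alongside for comparison rather than forcing
either convention. Species with a single replicate are excluded with a
warning; fewer than two species per group is an error, since a one-species
"group mean" would silently change the estimand.

Multiplicity is handled per compound family (carbohydrates: glucose,
fructose, sucrose, maltose, total; amino acids: proline, glycine, leucine,
total) by Bonferroni: family alpha 0.05 divided by family size, e.g. 0.01
for a five-compound family. Compounds missing in more than half the
replicates are excluded before the family is formed, mirroring the a-priori
exclusion of sparsely detected metabolites. "Total" compounds default to
sums over all detected compounds per sample (`total_concentration()`),
configurable to a focal subset.

## The synthetic-data generator

`simulate_season()` provides a no-download test surface with known truth.
Defaults were chosen once to emulate the motivating study's conditions:

- weekly survey days over ordinal days 153–281 (one Pollard-walk transect
  day per week);
- Gaussian flight curves truncated to the season, male peak day 180
  (mid-June emergence), female peak 14 days later, 12-day SD per sex;
- ~150 expected visits per sex per year (a ~6500-observation record over
  21 years and two sexes);
- a shared per-year phenology shift (SD 5 days) applied identically to
  both sexes, so equal-sex configurations remain exchangeable and hence
  usable for null-calibration tests; an *additional* independent per-sex
  shift (`sex_shift_sd`, default 0) can be switched on to emulate
  interannual variation in sex-specific life-history timing, the
  mechanism that makes the median-date gap — and with it foraging
  dissimilarity — vary between years;
- six focal plant species with staggered trapezoidal bloom curves (linear
  ramps to a plateau; the minimal shape that produces seasonal turnover
  and phenologically "forbidden" pairings) and sex-specific preference
  weights under which milkweeds leant male and the thistles, beebalm and
  knapweed lean female;
- a fraction (default 0.25) of the two thistle congeners' records masked
  to "Cirsium spp." for the assignment stage, with truth retained.

Visit counts per sex-day are Poisson with the flight-curve intensity;
each visit's plant is multinomial with probability proportional to bloom
availability on that day times the sex's preference weight.
`simulate_nectar_panel()` draws concentrations log-normally with
moment-matched species-specific means and SDs (SD 0 yields constant
replicates) and supports an additive group shift for recovery tests and
unequal replication (13 replicates for most species, 8 for one, matching
a realistic panel design).

What the generator does *not* emulate — and therefore what passing tests
cannot show about real data: observer effort variation and detection bias,
within-day revisitation and flight paths, floral abundance (availability
is a shape, not a density), weather-driven survey gaps, female
reproductive-diapause skew in the flight curve (off by default to keep
nulls calibratable), and any correlation between nectar chemistry and
visitation. Tests against the generator validate the *statistical
machinery*, not ecological conclusions.

## Numerical and design choices

- Quantiles: type 7 (linear interpolation) everywhere, documented because
  percentile bands on 1000 discrete null values differ visibly between
  quantile types.
- Lower-median convention for even-count median dates: deterministic and
  always an observed day.
- Week bins anchored at day 1, inclusive day-resolution window bounds.
- Chi-squared without continuity correction (2 × S tables with large
  pooled counts).
- Patefield sampling is vectorized across replicates for 2-row tables
  (one conditional-hypergeometric draw per column per batch), keeping
  1000-replicate null tests on 21 years well under a second.
- Problem sizes in the test suite were chosen to give sampling-theory
  margins at modest cost: 400 simulated years for null calibration, 40 for
  power, 50 for mixed-model recovery, 1000 replicates for p-value
  uniformity, 10^5 draws for sampler exactness.

## Known limitations

- The day-threshold classifier uses ordinal day only; a year-aware
  classifier could adapt to interannual phenology shifts but would be
  harder to audit.
- The heterogeneous-variance contrast assumes within-species normality;
  with 8–13 replicates per species, strong skew would distort the
  Satterthwaite df.
- Percentile null bands from 1000 replicates have quantile noise of a few
  percent at the tails; borderline classifications near the band edge
  should be read accordingly.
- Visitation is treated as preference-weighted availability sampling;
  without independent floral-abundance data the pipeline measures
  *association*, not preference.
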