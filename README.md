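# sexforage

Sex-specific floral visitation and nectar chemistry analysis for
long-term pollinator monitoring data.

Male and female flower-visiting insects often forage differently — and in
protandrous species, where males emerge weeks before females, part of any
difference is simply phenology: the sexes fly through different flowering
communities. `sexforage` takes a multi-year table of individual nectaring
observations (`year, ordinal_day, sex, plant_species[, count]`) and
separates the two signals:

- **Diversity.** Per sex-year species richness and effective species
  number `exp(H)` (the Hill number of order 1, with `H` Shannon entropy on
  natural logs), compared between sexes with the linear mixed model
  `metric ~ sex + (1 | year)` (REML, Satterthwaite df), plus residual
  ACF / Durbin–Watson diagnostics for interannual autocorrelation.
- **Composition.** Per-year Morisita–Horn dissimilarity between the
  female and male plant assemblages,

  d_mh = 1 − 2·Σxᵢyᵢ / [(Σxᵢ²/X² + Σyᵢ²/Y²)·X·Y],

  tested against 1000 fixed-margin random tables (Patefield's algorithm,
  the permutation null for interaction tables) with a 95% percentile null
  band and an above / within / below classification per year.
- **Phenological overlap.** Weekly female-share series, per-year overlap
  windows (first through last week with 25–75% female observations, with
  sparse windows excluded), and a re-run of every analysis on the
  overlap-restricted data — differences that survive the restriction are
  not attributable to phenology alone. A post-hoc regression of yearly
  d_mh on the female–male median-date gap quantifies the phenological
  contribution.
- **Association and nectar chemistry.** A pooled 2×S chi-squared test with
  Pearson residuals labels each plant female- or male-associated; nectar
  metabolite concentrations of the labeled species are then contrasted
  (female-group mean minus male-group mean) under a heterogeneous-variance
  model with Welch–Satterthwaite df, 4-SD leave-one-out outlier screening,
  and Bonferroni families for carbohydrates and amino acids.
- **Synthetic data.** `simulate_season()` / `simulate_nectar_panel()`
  generate protandrous seasons (Gaussian flight curves, trapezoidal bloom
  turnover, sex-specific preferences, genus-level label masking) and
  metabolite panels with known truth, so every stage is testable without
  any field data. Ambiguous congener records ("Cirsium spp.") are resolved
  by a maximum-margin day-threshold classifier fitted to unambiguous
  records.

## Worked example

Simulate a 21-year study under the default protandrous conditions and run
the full pipeline:

```r
library(sexforage)

sim    <- simulate_season(season_config(), seed = 2024)
cfg    <- pipeline_config(n_reps = 1000, seed = 2024)
bundle <- run_pipeline(sim$data, cfg = cfg)
print(bundle)
```

```
== Sex-specific foraging report ==
Visitation dataset: 6205 records, 6205 total visits, 7 plant species
  unassigned ambiguous records: 366
  duplicated rows (legal, kept): 4840
  ...

Full season:
  mean d_mh = 0.362; above-null years: 21 of 21
Sex comparison of effective_species_number over 21 paired years ( paired_t )
  female - male = 0.506 (SE 0.122), t(20.0) = 4.15, p = 0.000495
  female larger in 17 of 21 years
Sex-plant association: chi2 = 1414.21, df = 5, p = 1.15e-303
  female-associated: Centaurea stoebe, Cirsium discolor, Cirsium pumilum, Monarda fistulosa
  male-associated:   Asclepias syriaca, Asclepias tuberosa

Overlap period ( 8 of 21 years retained):
  mean d_mh = 0.267; above-null years: 8 of 8
Sex-plant association: chi2 = 284.14, df = 5, p = 2.57e-59
  ...
Dissimilarity ~ |median F day - median M day| (n = 21 years)
  slope = -0.002129, R2 = 0.010 (adj -0.042), p = 0.672
```

Reading the report: every simulated year's female–male dissimilarity sits
above its fixed-margin null band (the sexes' plant use differs more than
random re-pairing of visits allows), females visit ≈0.5 effective species
more than males, and the two milkweeds come out male-associated while the
thistles, beebalm and knapweed come out female-associated — the structure
the generator's preference weights encode. Restricting to the weeks when
both sexes were active shrinks mean dissimilarity from 0.36 to 0.27 but
does not erase it, which is the signature of a foraging difference beyond
phenology. The 366 genus-level thistle records were resolved by the day
threshold before analysis. (The mixed model for this draw collapses to a
paired t-test because the between-year variance is estimated at zero; the
report says so.)

A ready-made command-line wrapper for CSV inputs is installed at
`inst/scripts/run_pipeline.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/run_pipeline.R", package="sexforage"))')" \
  --input visits.csv --seed 1 --out report_dir
```

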