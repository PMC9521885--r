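# sdsens

Scoring neighborhood sensitivity to social distancing non-compliance from
establishment visit streams and resident complaint reports.

When a city relies on resident complaints (e.g. a 311 platform) to enforce
social distancing rules, neighborhoods that tolerate more crowding before
reporting are systematically under-represented in the complaint stream —
and so under-served by complaint-driven enforcement and outreach. `sdsens`
quantifies that differential sensitivity for epidemiologists, urban health
researchers and city analytics teams working with POI foot-traffic and
complaint data.

## The model

Each scoring unit is a building pooling one or more points of interest
(POIs). Hourly visits are binned to six-hour intervals, and each open
interval is flagged if a complaint was reported during it. With activity
intensity *I* = visits per 10,000 sq ft per interval, the package computes
per unit:

- **absolute threshold** *A* — mean intensity over complaint-flagged open
  intervals (the average stimulus that provoked a response);
- **difference threshold** *D* = (*A* − *B*)/*B* — the Weber fraction, the
  fractional excess over the unit's baseline mean intensity *B* (open,
  complaint-free intervals);
- **subjective sensation** *SS* = *D* · log₁₀ *A* (Fechner's law);
- **SDS score** = |1 − (SS − min SS)/(max SS − min SS)| × 100, the inverse
  min–max rescaling over all scored units: 100 = most sensitive, 0 = most
  tolerant.

Scores are averaged by zip code and fed to a disparity analysis: quartile
classification, one-way ANOVA with Tukey post-hoc across quartiles, Pearson
correlation with health indicators, and Welch t-tests of demographic shares
across police-response strata. Because the real inputs for this kind of
study are proprietary, the package includes a synthetic-city generator with
planted per-zip reporting thresholds θ_z, so the whole pipeline is testable
against known ground truth.

## Worked example

The textbook two-case example: two establishments share a baseline of 4
visits per interval (at 10,000 sq ft). One draws a complaint at 20 visits,
the other already at 6:

```r
library(sdsens)
baseline <- activity_intensity(rep(4, 8), 10000)
difference_threshold(absolute_threshold(20), baseline)
#> [1] 4
difference_threshold(absolute_threshold(6), baseline)
#> [1] 0.5
```

The first unit needed a 400% excursion over baseline before anyone reacted;
the second only 50%, so it is the more sensitive case and receives the
higher SDS score. At city scale:

```r
cfg <- city_config(n_zips = 4, pois_per_zip = 10, study_end = "2020-04-27",
                   seed = 42)
city <- generate_city(cfg)
city
#> Synthetic city: 40 POIs in 4 zips; 28800 hourly visit rows; 304 complaints

pooled <- pool_to_buildings(city$poi, city$visits)
iv <- flag_complaints(bin_six_hour(pooled$visits, pooled$units), city$complaints)
fit <- sds_fit(iv, pooled$units)
summary(fit)
#> Social distancing sensitivity fit: 36 units, 4 zips
#>   absolute threshold A: mean 42.24 [95% CI 33.41-51.08]
#>   difference threshold D: mean 1.52 [95% CI 1.20-1.83]
#>   SDS quantiles:
#>     0%    25%    50%    75%   100%
#>   0.00  53.90  76.92  84.97 100.00

fit$zip_scores
#>    zip    SDS_z n_units
#> 1 Z001 85.15304      10
#> 2 Z002 78.50373      10
#> 3 Z003 50.54831       9
#> 4 Z004 31.84259       7
```

The planted thresholds for these four zips rise from θ = 0.05 (complain at a
5% excursion) to θ = 1.5 (only react when activity is 2.5× baseline), and
the recovered zip scores fall in exactly that order. `classify_quartiles()`,
`compare_groups()`, `correlate_indicators()` and `compare_police_by_group()`
take the analysis from scores to disparity tables, and
`run_sds_pipeline(default_run_config())` runs every stage end to end,
writing CSVs, a filter ledger and a reproducibility manifest.

## Package layout

- `R/` — generator (`city_config`, `generate_city`), ingestion
  (`load_tables`, `pool_to_buildings`, `bin_six_hour`, `flag_complaints`),
  estimator (`sds_fit` and methods), neighborhood analysis, pipeline.
- `vignettes/sensitivity-scoring.Rmd` — the model, its assumptions, the
  generator's design and its limits.
- `tests/testthat/` — unit, property and end-to-end suites, including an
  independent straight-loop oracle for the scoring chain.
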