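# dietclust

Data-driven dietary pattern discovery and hypertension association analysis
for ordinal diet-history questionnaires.

Nutrition cohorts commonly record diet as ordinal frequencies: 58 food and
beverage items, 12 dietary behaviors, and 9 cooking methods (79 variables on
2/5/7/8/9-point scales). `dietclust` derives *dietary patterns* from that
matrix without any prior food grouping, then asks whether the patterns
predict incident hypertension:

1. **Cohort stage** — schema-validated ingestion, clinical covariate
   derivation (BMI = weight/height²; hypertension at SBP ≥ 140 mmHg,
   DBP ≥ 90 mmHg, or history/medication; diabetes at FBG > 126 mg/dL;
   dyslipidemia at LDL ≥ 140, HDL < 40, or TG ≥ 150 mg/dL), and an ordered
   exclusion cascade with first-step attribution.
2. **Pattern stage** — UMAP (n_neighbors = 10, min_dist = 0.1, Chebyshev,
   2D; implemented in-package with a seeded Rcpp optimizer) followed by
   K-means, with the cluster number selected jointly by the WCSS elbow,
   mean silhouette, and the mode count of a 2D Gaussian KDE of the
   embedding.
3. **Trend scores** — each cluster × variable is summarized by
   Σᵢ ωᵢπᵢ, the category weights ω (1 = lowest consumption) times the
   within-cluster category proportions π; equal to the cluster's mean
   mapped weight, with a one-way ANOVA across clusters per variable.
4. **Association stage** — per-cluster prevalence, crude cross-product odds
   ratios with 95% Wald CIs, and nested logistic Models 1–5 (cluster →
   +age, BMI → +smoking, education, physical activity → +dyslipidemia,
   diabetes → +salt intake) with model-level likelihood-ratio p-values.
5. **Sensitivity** — age-caliper matched reruns (±0 and ±2 years) and a
   DASH diet-score comparison (8 components scored 1–5 by cohort quintile,
   restricted components reversed, totals 8–40).

A synthetic cohort generator (`paper_like_preset()`) plants four patterns
with realistic mixing, age imbalance, covariates and outcome rates, so the
entire pipeline is testable end-to-end without restricted data.

## Worked example

```r
library(dietclust)
run <- run_pipeline(scenario = paper_like_preset(), out_dir = "results",
                    seed = 1)
print(run)
#> Pipeline run (seed 1 )
#> Exclusion cascade: 447 -> 447 participants
#>   ...
#> Selected k = 4 (diagnostics agree)
#> Outcome by cluster (reference: C )
#>                  A      B      C      D
#> cases         9.00   8.00  26.00  14.00
#> noncases     71.00 101.00 115.00 103.00
#> n            80.00 109.00 141.00 117.00
#> prevalence % 11.25   7.34  18.44  11.97
#>   cluster   or ci_low ci_high model
#> 1       A 0.56   0.25    1.27 crude
#> 2       B 0.35   0.15    0.81 crude
#> 3       D 0.60   0.30    1.21 crude
```

All three diagnostics agreed on four clusters, matching the four planted
patterns (cluster letters are ordered by embedding coordinate, so the
pattern-to-letter mapping varies by seed). The highest-prevalence cluster
(here C, 18.4%) is taken as the reference "aversive" pattern; the other
patterns show crude odds ratios below 1 against it. Model 1–5 tables,
matched-cohort reruns, the trend-score table, the embedding, k-selection
diagnostics and a manifest are written under `results/`.

Cluster character is read off the trend-score table:

```r
rk <- rank_clusters(run$trend)
head(rk[rk$n_max > 0, ])
#>   cluster         category n_max n_total        summary
#> 1       A        food_item    10      58    10/58 items
#> 2       A dietary_behavior     6      12 6/12 behaviors
#> 4       B        food_item     9      58     9/58 items
#> 7       C        food_item    12      58    12/58 items
#> 9       C   cooking_method     5       9    5/9 methods
#> 10      D        food_item    27      58    27/58 items
```

## Command line

A thin wrapper over the same functions ships in `inst/scripts`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/run_pipeline.R", package="dietclust"))')" \
  --cohort cohort.csv --schema schema.yaml --out results/ --seed 1
```

The packaged questionnaire schema is at
`system.file("extdata/bdhq_schema.yaml", package = "dietclust")`, with a
20-row synthetic example cohort beside it.
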