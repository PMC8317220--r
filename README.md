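# obesotype

Unsupervised metabolic subtyping of obesity cohorts from three routine
clinical variables: the OGTT glucose and insulin areas under the curve and
serum uric acid.

Obesity is clinically heterogeneous, but routine classification reduces it
to BMI bands or a binary healthy/unhealthy label. This package implements a
machine-learning subtyping pipeline for endocrinologists and biostatisticians
working with OGTT-profiled cohorts: it discovers four metabolic subtypes,
ports the fitted model to external cohorts, and quantifies how stable the
subtype structure is across cohorts.

## The model

Each patient is summarized by the feature vector

- glucose AUC = 15·g₀ + 30·g₃₀ + 45·g₆₀ + 30·g₁₂₀ (mmol/L·min, trapezoidal
  rule on the 0/30/60/120 min OGTT grid),
- insulin AUC, same rule (mU/L·min),
- uric acid (μmol/L).

Features are z-normalized within each sex stratum (sample SD) and each
stratum is clustered separately — k-means (Lloyd, k-means++ starts, 20
restarts, max 30 iterations, tolerance 1e-5) with the cluster count chosen
by maximum mean silhouette width, or two-step clustering (log-likelihood
inter-cluster distance, Schwarz-BIC-guided count selection). Centers are
mapped to subtypes by a deterministic rule: max glucose AUC → **LMO**
(hypometabolic), then max insulin AUC → **HMO-I** (hyperinsulinemic), then
max uric acid → **HMO-U** (hyperuricemic), remainder → **MHO**
(metabolically healthy).

External cohorts are assigned to a fitted model by nearest center in the
model's normalized space; agreement with an independent clustering is
reported, after optimal label matching, as per-cluster one-vs-rest
accuracy/sensitivity/specificity and Jaccard coefficients (mean Jaccard
\> 0.750 reads as stable clustering).

Supporting modules: AUC imputation from partial OGTT sampling (stepwise
regression, partial-F p \< 0.05 in / p \> 0.10 out, 70/30 held-out adjusted
R²), insulin sensitivity/secretion indices (HOMA-IR, HOMA-β, IGI, Matsuda
WBISI, disposition indices), comorbidity statistics (sex- and age-adjusted
odds ratios with Wald CIs, chi-square, ANOVA/ANCOVA with Bonferroni post
hoc), and a synthetic-cohort generator calibrated to the published subtype
geometry so the whole pipeline is testable without patient data.

## Worked example

```r
library(obesotype)

g   <- generate_cohort(default_config(), seed = 1)   # n = 882, published geometry
fit <- fit_sex_stratified(g$cohort, "kmeans", seed = 2)
fit
#> <cluster_model> algorithm: kmeans, k = 4, mean silhouette = 0.629
#> -- male centers (raw units):
#>       glucose_auc insulin_auc uric_acid
#> HMO-U         990       19522       588
#> MHO           986       17049       409
#> LMO          1845       10131       412
#> HMO-I        1002       49371       502
#> -- female centers (raw units):
#>       glucose_auc insulin_auc uric_acid
#> LMO          1837        9428       359
#> HMO-I        1099       55062       407
#> HMO-U        1100       21884       457
#> MHO           925       12944       331
```

Silhouette selection found k = 4 in both sex strata, and the de-normalized
centers sit at the generator's means (e.g. male LMO glucose AUC 1845
mmol/L·min with low insulin AUC — the decompensated subtype). The pooled
partition recovers the subtype prevalences:

```r
table(fit$partition$subtype)[subtype_levels()]
#>   MHO HMO-U HMO-I   LMO
#>   419   256    71   136      # 47.5 / 29.0 / 8.0 / 15.4 %
```

A verification cohort is clustered independently and assigned to the fitted
model; the report mirrors a cross-cohort validation table:

```r
gv <- generate_cohort(default_config(n = 300), seed = 3)
vr <- verification_run(fit, gv$cohort, seed = 4)
vr$report
#> <assignment_report> n = 300
#>          assigned
#> reference MHO HMO-U HMO-I LMO
#>     MHO   121     0     0   0
#>     HMO-U   1    93     0   0
#>     HMO-I   0     0    32   0
#>     LMO     0     0     0  53
#>  cluster accuracy sensitivity specificity jaccard empty_flag
#>      MHO    0.997       1.000       0.994   0.992      FALSE
#>    HMO-U    0.997       0.989       1.000   0.989      FALSE
#>    HMO-I    1.000       1.000       1.000   1.000      FALSE
#>      LMO    1.000       1.000       1.000   1.000      FALSE
#> means: ACC 0.998, SEN 0.997, SPE 0.999, Jaccard 0.995
```

One misassigned patient out of 300: the mean per-cluster accuracy (0.998)
and Jaccard (0.995) are well above the 0.941 / 0.750 stability benchmarks.
Models serialize to JSON (`write_model()`/`read_model()`), cohorts to CSV,
and `aor_table()` produces the sex- and age-adjusted comorbidity odds
ratios per subtype against MHO.

See `vignettes/metabolic-subtyping.Rmd` for the model assumptions, the
synthetic-generator calibration, and the numerical design choices.

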