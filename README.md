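# cellscreen

Cellwise error detection benchmarks for observational growth data.

Observational datasets — clinical registries, audits, cohort studies —
accumulate data-entry and measurement errors that are expensive to chase
through source-document verification. `cellscreen` provides a controlled
test bed for *cellwise* error screening: it simulates realistic
height/weight cohorts for individuals aged 2–20 years, plants errors of
known type and location in the height variable, runs a panel of detection
methods, and scores each method against the ground truth.

## What it implements

**Simulation.** Heights and weights follow the LMS growth-chart model: at
standard-normal deviate *Z*, a measurement is *M*(1 + *LSZ*)^(1/*L*), with
age- and sex-specific Box-Cox power *L*, median *M*, and generalized
coefficient of variation *S*. A reader for CDC-style LMS CSV files is
included, plus a builtin synthetic fallback table so everything runs with
no external data. Heights are recorded in whole centimetres; weights are
analysed on the natural-log scale.

**Error patterns.** Four mechanisms mimicking real failures: skip the last
digit (176 → 17), swap the last two digits (163 → 136), add 40 cm
(unit/calibration shift), or replace with a draw from below the age- and
sex-specific first percentile (implausibly short stature). Errors hit a
configurable fraction (2% or 10% in the study grid) of randomly chosen
height cells.

**Detectors.**

| method | score | flag rule |
|---|---|---|
| robust SDS | (x − median)/(1.4826·MAD) | \|SDS\| > 2 |
| boxplot | — | outside (Q1 − 1.5·IQR, Q3 + 1.5·IQR) |
| bagplot (×2 pairs) | Tukey halfspace depth | outside the bag inflated ×3 |
| Mahalanobis (classic, MCD, MVE) | squared distance on (age, height, log weight) | d² > χ²₃,₀.₉₉ |
| DetectDeviatingCells | standardized cell residual | \|residual\| > √χ²₁,₀.₉₉ |

The DetectDeviatingCells detector predicts every cell from the variables it
is robustly correlated with (|r| ≥ 0.5 by default), and flags cells whose
robust standardized residuals exceed the tolerance cutoff — so it localizes
the anomaly to a single value instead of condemning the whole record, and
its predicted values double as conditional-mean replacements. The MCD and
MVE searches are in-package implementations of the usual stochastic subset
algorithms (concentration steps / minimal covering ellipsoid).

**Evaluation.** Cell-level sensitivity, specificity, PPV and LR+ with
exact (Clopper–Pearson) or log-method 95% intervals; ROC curves with
Mann–Whitney AUC and DeLong intervals; Youden-index optimal cutoffs.

## Worked example

```r
library(cellscreen)

stature <- builtin_lms_table("stature")
weight  <- builtin_lms_table("weight")

cfg <- scenario_config("add_shift", prevalence = 0.02, n = 5000,
                       methods = c("sds", "maha_mcd", "ddc"), seed = 2026)
res <- run_scenario(cfg, stature, weight)
subset(res$metrics, metric %in% c("sensitivity", "specificity"))
res$auc[, c("method", "auc", "youden_se", "youden_sp")]
```

```
       scenario   method      metric estimate ci_low ci_high
 add_shift_2pct      sds sensitivity    0.140 0.0787   0.224
 add_shift_2pct      sds specificity    1.000 0.9989   1.000
 add_shift_2pct maha_mcd sensitivity    0.960 0.9007   0.989
 add_shift_2pct maha_mcd specificity    0.850 0.8395   0.860
 add_shift_2pct      ddc sensitivity    0.970 0.9148   0.994
 add_shift_2pct      ddc specificity    0.983 0.9795   0.987

   method   auc youden_se youden_sp
      sds 0.723      0.51     0.870
 maha_mcd 0.959      0.95     0.861
      ddc 0.998      0.97     0.992
```

Reading: a 40-cm shift leaves most corrupted heights inside the pooled
height range, so the univariate SDS rule finds only 14% of them; the
robust multivariable methods exploit the age–height–weight correlation and
find 96–97%, with the cellwise detector keeping by far the best
specificity. `run_study()` crosses all four patterns with both prevalences
and returns the descriptive, metric and AUC tables plus a manifest of
seeds that reproduces every scenario bit-identically.

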