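---
title: "Cellwise error screening in simulated growth data: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cellwise error screening in simulated growth data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellscreen)
```

# The problem

Error screening in observational data must trade false alarms (genuine
values sent for verification) against misses (errors that survive into
analysis). Univariate rules are cheap but blind to errors that are only
implausible *in context* — a 130 cm height is unremarkable until you know
the patient is 19 years old and weighs 70 kg. Multivariable rules exploit
that context but usually condemn a whole record without saying which value
is wrong. Cellwise detection aims at the best of both: flag the individual
cell, using the multivariable structure.

`cellscreen` builds a fully controlled laboratory for this comparison:
a growth cohort whose joint (age, height, weight) structure is realistic,
an error process whose ground truth is known exactly, a panel of seven
detectors, and a common evaluation layer.

# Simulation model

Within each (age in months, sex) group a measurement is generated by the
LMS (Box-Cox) model

$$x = M \,(1 + L S Z)^{1/L}, \qquad Z \sim N(0,1),$$

with the limiting form $M e^{SZ}$ at $L = 0$. $M$ is the group median (cm
or kg), $S$ the generalized coefficient of variation, and $L$ the Box-Cox
power governing skewness. Records are allocated evenly across all groups
(ages 24–240 months, both sexes); any remainder is assigned round-robin in
group sort order so that allocation is independent of the seed. The height
and weight deviates of a record are drawn independently: the strong
height–weight correlation in the pooled cohort is induced by the shared
age/sex structure, and no further within-record dependence is modelled.

Heights are rounded to whole centimetres. This is how stature is recorded
in practice, and two of the error patterns ("skip last digit", "swap last
digits") are only well defined on a digit string. Weight stays continuous
and enters all analyses as its natural logarithm, which removes most of
the skewness that would otherwise degrade the symmetric flagging rules.

## The builtin fallback table

A synthetic LMS table ships with the package so that nothing requires a
download: $L = 1$ (normal within each group), medians piecewise-linear in
age between yearly anchors chosen to track typical paediatric growth
(male stature 86.9 cm at 24 months to 176.8 cm at 240 months, with the
pubertal acceleration between 12 and 15 years; analogous weight anchors),
and constant $S$ per measure — 0.042 for stature, 0.18 for weight. These
values were fixed once, from general knowledge of paediatric
anthropometry, as what a practitioner would call a realistic cohort.

What the fallback does emulate: the age/sex group structure, the pooled
height distribution's location and robust spread, the strong age–height
and height–log-weight correlations, and integer-cm recording. What it does
not: the within-group skewness of real growth references ($L \neq 1$,
age-varying $S$), the half-month age grid of chart files, and any
height–weight dependence beyond age. Consequently, results on the fallback
table are qualitatively faithful (ordering of methods, ceiling effects,
masking of the non-robust distance) but individual sensitivities can sit
at the favourable end of, or slightly outside, intervals published for
chart-based cohorts: symmetric within-group distributions make planted
errors a little easier to separate. The test suite treats the
ceiling/ordering claims as exact and the chart-based point values as
interval checks, and the ones that depend on chart geometry are the ones
that can fail on the fallback table. A CDC-format LMS file, when supplied
via `load_lms_table()`, slots into every function unchanged for fidelity
runs.

# Error process

Exactly `round(prevalence * n)` height cells are drawn uniformly without
replacement (half-up rounding; at the study's n = 5000 and 2%/10% the
product is integral anyway). Four patterns:

* **skip_last_digit** — integer division by 10. A gross error: corrupted
  heights (8–24 cm) are disjoint from plausible statures, so every
  reasonable method should reach 100% sensitivity; it calibrates the
  ceiling rather than discriminating between methods.
* **swap_last_digits** — transpose the last two decimal digits. When the
  two digits are equal the value is unchanged, but the cell stays in the
  error mask: the corruption was applied even if invisible. This caps
  attainable sensitivity for the pattern (about one height in ten ends in
  a repeated digit) and is the deliberate interpretation of "swap".
* **add_shift** — add a constant (default 40 cm, roughly 1.5 pooled SDs of
  height): errors remain individually plausible but sit in the wrong part
  of the age–height relationship.
* **sample_first_percentile** — replace with a draw from
  $N(M, (MS)^2)$ truncated above at the group's first percentile
  $P_1$, by inverse-CDF: $h = \mu + \sigma\,\Phi^{-1}\!\big(U\,\Phi((P_1-\mu)/\sigma)\big)$,
  rounded to whole cm. The untruncated mean/sd $(M, MS)$ is the natural
  normal approximation to the group's LMS distribution; the reference
  study does not specify one, so this choice is recorded here as this
  package's concretization. These errors are individually plausible
  heights and are only detectable through weight and age context — the
  hardest pattern by construction.

Cells outside the mask are bit-identical before and after contamination;
the suite asserts this exactly.

# Detectors

**Robust SDS.** $(x - \mathrm{median})/(1.4826\,\mathrm{MAD})$, flag
outside $(-2, 2)$, strict at the boundary. Applied to the pooled height
column, not age-stratified — deliberately so: the pooled rule is what a
quick screening pass uses, and its weakness against context-dependent
errors is part of what the benchmark measures.

**Boxplot.** Tukey fences at $Q_1 - 1.5\,\mathrm{IQR}$ and
$Q_3 + 1.5\,\mathrm{IQR}$; quartiles by linear interpolation of the
empirical CDF (the `quantile()` type-7 convention — no convention is
stated in the reference study, and type 7 is R's default). Strictly
outside flags.

**Bagplot.** For the pairs (age, height) and (height, log weight). Tukey
halfspace depth is computed exactly per query point by sorting the angles
of all points around it and scanning every direction at which the closed
halfplane count can change (each data angle, its antipode, and the
midpoints between consecutive critical directions) — O(n log n) per
query. The bag is the convex hull of the deepest half of the points: the
smallest depth threshold retaining at most half (quasi-concavity of depth
guarantees the hull adds no shallower points); the fence inflates the bag
threefold about the depth median (mean of the maximal-depth points); flags
are strictly-outside-the-fence. This hull-of-deepest-points construction
approximates exact depth-contour interpolation; only the outside/inside
decision at the fence matters here, where the approximation is
immaterial. Duplicate (integer) points are deduplicated before the depth
sweep.

**Mahalanobis distances** on (age, height, log weight); sex is excluded as
a non-continuous variable. Classic: sample mean/covariance. MCD: FastMCD
search — 500 random (p+1)-subsets, two concentration steps each, full
C-step iteration (convergence at determinant change < 1e-9 or 100 steps)
for the ten most promising, then the standard consistency rescaling
$(h/n)/P(\chi^2_{p+2} \le q_{h/n})$. MVE: 500 random (p+1)-subsets, each
inflated to cover $h$ points, smallest volume wins, then chi-square-median
consistency scaling. Both use $h = \lfloor (n+p+1)/2 \rfloor$ by default —
the most robust admissible choice, recorded in the result object. Flags
at $d^2 > \chi^2_{3,0.99} \approx 11.345$, strict. Row flags are
attributed to the height cell, since errors exist only there.

**Cellwise detector (DetectDeviatingCells).** Deterministic, four steps:

1. *Standardize*: per column, median/1.4826·MAD; cells with $|z| > c$,
   $c = \sqrt{\chi^2_{1,\mathrm{tolProb}}}$ (≈ 2.576 at the default
   tolProb = 0.99), are set aside for the estimation steps.
2. *Correlate*: product-moment correlation on pairwise-complete trimmed
   columns (the robustness comes from the trimming); pairs with fewer
   than 3 complete rows get 0. Column $k$ informs column $j$ when
   $|r_{jk}| \ge$ corrlim (default 0.5).
3. *Predict*: per connected pair, a slope as the median of cellwise
   ratios $z_{ij}/z_{ik}$; per cell, the $|r|$-weighted mean of slope
   predictions over available connected columns; per column, a
   deshrinkage factor (median ratio of observed on predicted) undoes the
   attenuation of the median-of-ratios slope.
4. *Flag*: residuals $z - \hat z$ are robustly standardized per column
   (median-centered, 1.4826·MAD-scaled, estimated over the cells that had
   at least one usable predictor; the scale is floored at 1e-8 so exact
   linear dependencies still yield flags); $|r^{std}| > c$ flags the
   cell. Cells with *no* usable predictor — standalone columns, or rows
   whose connected cells were all set aside — fall back to the univariate
   criterion: their standardized residual is their own $z$-score.

The original algorithm leaves several estimators to its reference
implementation; trimming-based correlations, median-of-ratio slopes and
deshrinkage are this package's recorded concretization. One practical
consequence, visible in the study grid: hard trimming is very robust, so
this variant resists 10% contamination more than implementations that
merely downweight outlying cells, and its sensitivities under heavy
contamination can exceed published values for the original.

Residual centering in step 4 deserves a note: contaminating a column
shifts its median slightly, which leaves a small constant offset in every
residual of a connected column. Scaling without centering turns that
offset into mass false flagging whenever the residual spread is small;
centering at the median removes it and is what makes the exact-dependence
property (precision = recall = 1 on a proportional pair with a few
corrupted cells) hold.

Predicted values are returned in data units — the conditional-mean
replacement that makes the method usable for single imputation — but
their quality as corrections is deliberately not evaluated here.

*Rowwise statistic.* $T_i$ = mean over columns of the $\chi^2_1$ CDF of
the squared standardized residual, flagged when its robust z-score
exceeds $c$. With very few columns this statistic saturates: $T_i \in
[0,1]$, and at $p = 3$ even a fully corrupted row's robust z-score stays
near 2, below $c$ — rowwise flagging only becomes powerful from roughly
six columns up. The study's evaluation is cellwise, so this limitation is
documented rather than patched.

# Evaluation

All performance is computed at cell level against the mask. Sensitivity,
specificity and PPV carry Clopper–Pearson exact intervals
(`binom.test`); LR+ = Se/(1−Sp) carries the log-method interval
$\exp(\log \mathrm{LR} \pm 1.96\,\hat\sigma)$ with
$\hat\sigma^2 = 1/tp - 1/(tp+fn) + 1/fp - 1/(fp+tn)$ — the interval type
is not stated in the reference study, so both choices are recorded here.
ROC curves come from `pROC` with fixed direction (higher score = error),
AUC equal to the Mann–Whitney statistic with the half-tie convention, and
DeLong 95% intervals. The Youden index $J = Se + Sp - 1$ is maximized
over the curve; ties are broken toward higher specificity (fewer
verifications for the same J). ROC scores: |SDS|, squared distances, and
the |standardized residual| of the height cell; boxplot and bagplot are
threshold-only and excluded from ROC, as in the reference study's
tables. The suite cross-checks AUC against exhaustive pair counting and
the Youden point against a brute-force sweep, and verifies that every
fixed-threshold (Se, Sp) lies on its method's ROC curve.

# Orchestration and reproducibility

`run_scenario()` feeds one contaminated cohort to all methods (paired
comparison); a failing method is isolated and reported, not fatal.
`run_study()` crosses the four patterns with both prevalences, sharing
one error-free cohort per replicate, and derives per-scenario seed
streams from the master seed so simulation, contamination and the MCD/MVE
searches never perturb one another. The manifest it returns reproduces
any scenario bit-identically; the suite asserts this.

Problem sizes: the study grid uses n = 5000, the size the benchmark is
designed around; orchestration unit tests use n = 400–800 and reduced
subset-search effort (enough for the structural contracts they check);
oracle comparisons use n ≤ 50 for depth and n ≤ 200 for AUC, where
exhaustive enumeration is exact; null-rate checks use 3000 × 3 matrices.
Interval (fidelity) checks run two replicate seeds at full study scale.

# Known limitations

* The fallback table's within-group normality makes some chart-calibrated
  interval checks sit high; supply a real LMS chart file for fidelity
  work.
* Errors are planted in one variable only, independently at random;
  correlated error placement, multi-variable errors and missingness are
  out of scope.
* The bagplot bag is a hull-of-deepest-points approximation, not an
  interpolated depth contour; fine for fence classification, not for
  publication-grade bag geometry.
* Rowwise flagging is weak below ~6 columns (statistic saturation, above).
* The cellwise detector handles continuous variables only; categorical
  structure (e.g. sex) can only enter by stratification.
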