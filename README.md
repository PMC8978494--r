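# swbtrace

Predicting subjective well-being from digital traces.

`swbtrace` is an R implementation of a complete analysis pipeline that
predicts two self-reported well-being scales — the Satisfaction with Life
Scale (SWLS) and the WHO-5 Well-Being Index — from behavioral digital
traces: private-message streams, phone app-usage logs, and profile
metadata. It is written for computational social scientists and
biostatisticians who want to study (or stress-test) this class of digital
phenotyping analyses without access to private user data: a synthetic
cohort generator with planted, tunable effects makes every stage of the
pipeline runnable and testable end to end.

## What the package computes

**Scales and screening cutoffs.** Raw scores are normalized onto [0, 1]
via `(raw − 5)/divisor` (divisor 30 for SWLS, 25 for WHO-5). WHO-5 cutoffs
are validated against depression (PHQ-9 ≥ 10), anxiety (GAD ≥ 10) and
stress (PSS ≥ 21) screens, with low WHO-5 as the positive screen. The
binary cutoff maximizes the mean Youden *J* = sensitivity + specificity − 1
across the three conditions; trinary cutoffs are set by specificity and
sensitivity floors.

**Feature families.**

| family | count | contents |
|---|---|---|
| activity | 40 | demographics, message volumes, monthly alter counts, 3-hour circadian usage slots |
| app categories | 225 | 9 category totals + 72 category×slot values + two normalized variants |
| sentiment | 6 | positive/negative proportions over month / year / full history |
| lexicon categories | 8 | per-category TfIDF sums (Bio, Cognitive, Social, ...) |
| words | heldout-selected | TfIDF columns passing a p ≤ 0.01 univariate test on a disjoint cohort |
| word clusters | heldout-selected | supervision-regularized consensus clusters of word embeddings |

**Consensus word clustering.** Spherical KMeans over word embeddings with
an objective `J = cosine inertia + weight × Σ p-values` (the p-value of
each cluster feature's correlation with the target); ten restarts per
weight are combined by thresholded co-association into consensus
solutions (4 weights × 5 thresholds = 20 candidates, each with an
augmented twin that absorbs infrequent words), and the winner is chosen by
heldout RandomForest MAE.

**Evaluation harness.** Value-stratified 10-fold train/dev/test splits
(298/37/37 at n = 372), hyperparameter choice and recursive feature
elimination on the dev set, seven regression families and three
classification families, fold-averaged MAE / Pearson r / R² or F1 and
low-class TPR/FPR, baselines, and a stable-feature report (features
selected by RFE in ≥ 5 of 10 folds).

## Worked example

Validate WHO-5 screening cutoffs on a synthetic mental-health cohort:

```r
library(swbtrace)

cfg <- cohort_config(n_users = 417, seed = 42, message_rate = 0, usage_rate = 0)
cohort <- generate_cohort(cfg)
who5 <- normalize_score(scale_spec("WHO5"), cohort$users$who5_raw)
labels <- list(
  depression = binarize_condition(condition_spec("depression"), cohort$users$phq),
  anxiety    = binarize_condition(condition_spec("anxiety"),    cohort$users$gad),
  stress     = binarize_condition(condition_spec("stress"),     cohort$users$pss))

sel <- select_cutoffs(sweep_cutoffs(who5, labels))
sel$binary$cutoffs
#> [1] 0.46
cutoff_confusion(who5, labels$depression, sel$binary$cutoffs, "depression")
#>    condition cutoff   n  tp fp  tn fn sensitivity specificity undefined
#> 1 depression   0.46 353 140 32 113 68   0.6730769   0.7793103     FALSE
table(assign_class(who5, sel$binary))
#>  low high
#>  207  210
```

The selected cutoff (0.46 for this seed) sits near the generator's planted
screening boundary of 0.51; the confusion row reads as: of the 353 users
with a completed PHQ-9, 140 depression screen-positives also screen
positive on WHO-5 (sensitivity 0.67 at this cutoff) and 113 of the 145
negatives screen negative (specificity 0.78).

Predicting WHO-5 from behavioral features, with the planted circadian
effect recovered in the stable-feature report:

```r
co <- generate_cohort(cohort_config(n_users = 60, seed = 11,
                                    message_rate = 60, usage_rate = 40))
x <- cbind(behavior_features(co), app_features(co))
x <- x[, apply(x, 2, sd) > 0]
y <- normalize_score(scale_spec("WHO5"), co$users$who5_raw)
folds <- make_folds(y, n_bins = 10, seed = 1)
cv <- cv_regression(x, y, folds = folds, seed = 2,
                    specs = default_model_specs("regression",
                      rf_ntree = 100, ada_rounds = 20)[c("linear", "lasso", "rf")])
cv
#> Cross-validated regression report
#>   linear      mae=0.1244 pearson_r=0.7166 r2=0.1918
#>   lasso       mae=0.1416 pearson_r=0.5125 r2=-0.1028
#>   rf          mae=0.0942 pearson_r=0.7848 r2=0.5029
#>   mean_baseline mae=0.1524 pearson_r=0.0000 r2=-0.0556
#>   median_baseline mae=0.1507 pearson_r=0.0000 r2=-0.0812
#>   best: rf
head(stable_features(cv$models[[cv$best]], min_folds = 5), 3)
#>              feature n_selected mean_importance
#> 1        AppUsage0-3         10       0.2355859
#> 2   AppUsage0-3Ratio         10       0.2515808
#> 5 AppUsage18-21Ratio         10       0.1589636
```

The random forest beats both baselines, and the features it keeps in every
fold are the night-time (0–6 h) usage slots — exactly the circadian effect
the generator plants (low WHO-5 shifts usage mass into the night).

The methods vignette (`vignettes/swbtrace-methods.Rmd`) documents the
model, every design decision the analysis left open, the generator's
assumptions, and the numerical conventions.

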