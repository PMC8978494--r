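---
title: "Predicting subjective well-being from digital traces: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting subjective well-being from digital traces: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swbtrace)
```

## The problem

Self-reported subjective well-being (SWB) is usually measured with short
questionnaires: the Satisfaction with Life Scale (SWLS, raw range 5–35)
captures the cognitive evaluation of one's life, and the WHO-5 Well-Being
Index (raw range 5–30 under the coding used here) captures recent emotional
well-being and doubles as a depression-risk screen. Digital traces — private
messages, phone app-usage logs, profile metadata — carry behavioral signal
about both. `swbtrace` implements the full analysis pipeline for predicting
the two scales from such traces: scale scoring and screening-cutoff
validation, four families of trace-derived features, a
supervision-regularized consensus word-clustering method, and a stratified
cross-validation harness with recursive feature elimination (RFE), for both
regression on the continuous scales and classification of discretized WHO-5
levels.

Because real trace data of this kind are private, the package ships a
synthetic-cohort generator as a first-class, tested module. All statistical
guarantees quoted below are established on generated cohorts; what that does
and does not show about real data is discussed at the end.

## Scales

Both scales are normalized onto $[0,1]$ by subtracting 5 and dividing by the
scale width (30 for SWLS, 25 for WHO-5). The WHO-5 raw range is taken as
5–30 so that this affine map is exactly onto $[0,1]$; the canonical WHO-5
raw coding (0–25) differs by a constant, and only the normalization matters
downstream. Internal consistency is computed with Cronbach's
$\alpha = \frac{k}{k-1}\bigl(1 - \sum_i s_i^2 / s_T^2\bigr)$.

Normalized scores are discretized by `assign_class()` with the convention
that a score **at or above** a cutoff belongs to the upper class. The
convention is arbitrary but must be fixed; it is documented here and used
consistently, including at the binary default 0.51 and the trinary defaults
0.35/0.59. Reported normalized statistics are rounded half-to-even at four
decimals.

## Screening-cutoff validation

WHO-5 cutoffs are validated against three screening questionnaires
binarized at their published thresholds: depression (PHQ-9 $\ge 10$),
anxiety (GAD $\ge 10$) and stress (PSS $\ge 21$). A *low* WHO-5 score is
the positive screen (`who5_norm < cutoff`), since risk sits at the bottom of
a well-being scale. Users missing a questionnaire are excluded for that
condition only, so per-condition sample sizes differ.

The selection policy had to be made explicit, because "trying out
thresholds" admits many formalizations:

* **binary cutoff** — the grid value maximizing the mean Youden
  $J = \text{sensitivity} + \text{specificity} - 1$ across the three
  conditions;
* **trinary cutoffs** — the lower cutoff is the largest grid value whose
  mean specificity reaches a floor (default 0.8), so low-class calls are
  confident; the upper cutoff is the smallest grid value whose mean
  sensitivity reaches a floor (default 0.9), so few at-risk users land in
  the high class. Both floors are configurable; unsatisfiable floors raise
  an explicit failure flag rather than a silent fallback.

The default candidate grid is the set of midpoints between consecutive
distinct observed scores, which contains every cutoff that can change a
confusion table. Sensitivity is non-decreasing and specificity
non-increasing in the cutoff by construction; the test suite checks both
against an exhaustive-counting oracle.

## Linguistic features

**Sentiment proportions.** Six features: the proportion of positive and of
negative lexicon words among all tokens written in the trailing 30 days, the
trailing 365 days, and the entire history, measured backward from each
user's reference time. Windows with no tokens yield 0 for both polarities
(a documented convention; the alternative, NA, would only push the decision
into the imputation step).

**TfIDF.** The variant is the simplest textbook form:
$\text{score}(w,d) = \text{count}(w,d)\cdot\ln(N/\text{df}(w))$, with no
length normalization. Nothing downstream depends on the variant, and it is
isolated behind `fit_tfidf()`/`tfidf_matrix()` so it can be swapped. The
vocabulary keeps lemmas with corpus frequency at least `min_count`
(default 200, matching the scale of a year-long multi-user corpus; tests
use smaller values on small synthetic corpora).

**Word selection.** Open-vocabulary word features are selected on a
*heldout* cohort disjoint from the modeling cohort: for each word and each
target scale, the F-test of the univariate linear regression of the target
on the word's TfIDF column (equivalent to the two-sided Pearson test);
words with $p \le 0.01$ for either target are kept, and the union is the
modeling feature set. An "ANOVA against a continuous target" admits a
binned reading too; the univariate-regression reading was chosen because no
binning is defined anywhere else in the pipeline, and only this reading is
implemented. Zero-variance columns are excluded with a note. Word features
for the final cohort are re-scored under a TfIDF model refit on the final
cohort rather than carrying the heldout document frequencies over.

**Lexicon categories.** Eight category features (Bio, Cognitive, Social,
Time, Percept, Feel, Hear, See) are the sums of the user's TfIDF scores
over each category's lemmas, computed under an *unrestricted* vocabulary
(`min_count = 1`): infrequent words count toward category sums even though
they are never individual features.

## Supervision-regularized consensus word clustering

Word clusters are semantic features: embeddings (dimension 300 for real
word2vec models; synthetic tests use smaller dimensions) are clustered with
spherical KMeans (cosine distance on unit-normalized vectors, `k = 300` at
study scale). Three design points needed fixing:

1. **How the supervision penalty enters.** The penalty is
   $\sum_c p_c$, where $p_c$ is the two-sided p-value of the Pearson
   correlation between cluster $c$'s per-user TfIDF-sum feature and the
   target scale; zero-variance features count $p_c = 1$. The objective
   $J = \text{cosine inertia} + \text{weight}\times\text{penalty}$ is
   evaluated after every Lloyd iteration, and the argmin-$J$ iterate is
   returned. The penalty therefore steers the *choice among iterates*, not
   the assignment rule itself, which keeps Lloyd convergence behavior
   intact and reduces exactly to spherical KMeans at weight 0.
2. **Consensus construction.** For each regularization weight
   (grid 0, 50, 100, 500) ten random restarts are combined: the
   co-association fraction of every lemma pair is thresholded
   (grid 0.25, 0.45, 0.65, 0.75, 0.85) and consensus clusters are the
   connected components of the resulting link graph — the standard
   co-association recipe. Singleton components are allowed; thresholds
   above 1 give all singletons. Raising the threshold can only remove
   links, so higher thresholds refine the partition (tested property).
   The default grids give $4 \times 5 = 20$ consensus solutions.
3. **Augmented twins.** Each solution is paired with an augmented twin in
   which every infrequent word (below `min_count`, with embedding
   coverage) joins the cluster whose centroid — the mean of member
   vectors, renormalized — is nearest by cosine. Original memberships
   never change; uncovered lemmas are skipped with a message.

Candidates are compared on the heldout cohort: clusters correlating with
the target at $p < 0.05$ survive as features, and each candidate's
feature set is scored by the fold-averaged test MAE of a 10-fold
RandomForest regression with RFE. Since RFE needs a development signal
inside each training fold, a fifth of the fold's training users are carved
off as an internal dev set — a detail the evaluation design leaves open.
The candidate metadata row carries (regularization weight, consensus
threshold, infrequent-word flag, number of clusters, MAE); the cluster
count reported is the **post-filter** feature count, since that is the
quantity that enters the models. A candidate with no surviving cluster is
assigned infinite MAE and logged.

## Activity and app-category features

**Activity (40 features).** Demographics and profile counts (age, gender
coded male = 0 / female = 1, friend and subscription counts), trailing
30-day message count and character volume, monthly distinct-correspondent
counts for 12 consecutive 30-day windows ("months", per the design's
explicit 30-day definition, not calendar months), the count/duration/ratio
of app sessions in the observation week, and per-slot usage. The
month-over-month "weighted difference" has no published formula; the
symmetric relative difference $(v_1 - v_2)/(v_1 + v_2)$, bounded in
$[-1, 1]$ and 0 at $0/0$, is used for both message volume and alter
counts. `AllAlters` counts distinct correspondents over the 12 monthly
windows (360 days), which guarantees the invariants
$\max_m \text{Alters}_m \le \text{AllAlters} \le \sum_m \text{Alters}_m$.

**Circadian slots.** The day is cut into eight 3-hour slots
$[0,3), \ldots, [21,24)$ in a single configured clock (synthetic data
carries no timezone; real-data adapters must localize first). Sessions are
split **proportionally** across slot and midnight boundaries, so slot
totals conserve total usage exactly — an invariant asserted in the tests.

**App categories (225 features).** Packages map to nine categories
(unmapped packages fall to Other; the map ships as an editable TSV
contract). Features: 9 raw category totals over the whole window; 72
category-by-slot values averaged per day; 72 normalized by the category's
per-day total; 72 normalized by the slot's per-day total. The per-day
averaging denominator is the full window length (default 7 days), not the
number of active days — a stable scale across users. Category totals are
raw sums (not day-averaged): the two readings differ only by the constant
window length, and the raw total was chosen as the more interpretable of
the two. Both normalizations define $0/0 = 0$ and are tested to sum to 1
over their respective margins.

## Evaluation harness

**Folds.** The published bin-assignment formula (stride 37 into 10 bins of
37) cannot be taken literally — indices $i + 37K$ collide across bins — so
the design is reconstructed from its two stated properties: 10 equal bins,
each "equally distributed in terms of the SWB values". The sample is
shuffled (seeded, so ties break randomly but reproducibly), sorted by the
target, and sorted positions are dealt round-robin to the 10 bins; the
$n \bmod 10$ leftover users join every training set. Fold $i$ tests on bin
$i$ and develops on bin $i+1$ with wraparound at the last fold. At
$n = 372$ this yields the 298/37/37 train/dev/test design with pairwise
disjoint test bins covering 370 users. A leakage assertion runs on every
fold of every harness call.

**RFE.** From the full feature set, each round drops the lowest-importance
10% (at least one feature), refits, and records the dev error (MAE for
regression, $1 - \text{macro-}F_1$ for classification); the subset with the
best dev error wins (first minimum on ties, i.e. the larger subset).
Importances are coefficient magnitudes for linear families and split-based
importances for trees and ensembles.

**Models.** Seven regression families (linear, ridge, lasso, elastic net,
decision tree, random forest, AdaBoost.R2) and three classification
families (multinomial logistic, random forest, SAMME AdaBoost). The
AdaBoost variants are implemented in-package over `rpart` base learners
with case weights. Hyperparameter grids are small documented defaults
(three lambdas for the penalized linear families, two tree depths,
fixed ensemble sizes), chosen on the dev set by MAE (regression) or macro
$F_1$ (classification) before RFE runs with the winning values; all grids
are overridable per `model_spec()`.

**Metrics and reporting.** Regression: MAE, Pearson $r$ (defined as 0 when
a prediction is constant), $R^2 = 1 - \text{SS}_{res}/\text{SS}_{tot}$ on
the test set. Classification: macro and weighted $F_1$, per-class $F_1$
for the low and high classes, and the low class's true/false positive
rates, the screening-relevant pair. All aggregates are arithmetic means
over folds, recomputable from the stored per-fold metrics. Baselines:
train-mean and train-median predictors for regression, train-majority for
classification (for a majority-low sample this baseline shows
$\text{TPR}_{low} = \text{FPR}_{low} = 1$). Features selected by RFE in at
least five of ten folds form the stable-feature report, with importances
averaged over the folds where the feature was selected.

## The synthetic-cohort generator

The generator emulates the statistical structure the analysis assumes:

* **Scales.** A latent per-user well-being value follows a Beta
  distribution skewed low (mean 0.46, sd 0.19 on the normalized scale,
  matching a high-risk, help-seeking sample). SWLS and WHO-5 are
  Gaussian-copula transforms of a shared factor with latent correlation
  equal to `scale_corr` (default 0.568); after discretization onto the raw
  ranges, the realized correlation stays within a few hundredths of the
  target. Per-scale item scores are the raw total split by a symmetric
  Dirichlet, enabling internal-consistency computations without real item
  data.
* **Questionnaires.** PHQ-9/GAD/PSS are rounded, clipped linear-in-WHO-5
  scores with Gaussian noise, each missing at random at its own completion
  rate. Slopes and noise scales were fixed once, by forward calibration,
  so that the binary screening regime at cutoff 0.51 is realized: high
  sensitivity with moderate specificity at 0.51, very high specificity at
  0.35, very high sensitivity at 0.59, and a mean-Youden-optimal cutoff
  recoverable near 0.51.
* **Messages.** Counts are Poisson with a mild seasonal intensity over the
  365 days before the user's reference time; correspondents follow a
  Dirichlet-multinomial so alter counts vary. Tokens mix a Zipf-weighted
  neutral vocabulary, sentiment lemmas whose rates rise (positive) or fall
  (negative) with latent well-being, and planted-effect lemmas whose rates
  scale as $\exp(\delta z)$ in the standardized latent. The default rate
  of 2000 messages/user/year keeps cohort-scale simulation tractable while
  preserving the within-user corpus sizes the text features need; the
  real-world analogue is an order of magnitude larger, but no distributional
  conclusion in the package depends on the absolute rate.
* **App usage.** Session start hours follow a day/night mixture; the night
  (0–6 h) mass shifts with standardized WHO-5 by `circadian_effect`, so
  low-well-being users use their phones at night more. Sessions land
  exactly at their drawn clock hour within the 7-day window.

Every generator is bit-reproducible given `seed`, with per-user seeds
derived so that streams are independent across users.

**What passing tests do not show.** The generator plants exactly the
effects the pipeline looks for, with clean functional forms (linear links,
log-linear token rates, a single latent factor). Passing parameter-recovery
tests therefore demonstrates that the pipeline's machinery is correct and
calibrated — not that real digital traces carry this much signal, nor that
real lexical effects are linear in TfIDF. Real message text, conversation
structure, topic drift, multilingual content and timezone heterogeneity are
all outside the generator's scope.

## Numerical conventions and test scales

* $0/0$ ratios are 0 throughout (sentiment windows, slot and category
  normalizations, weighted growth).
* Zero-variance features: excluded with a note in word selection, $p = 1$
  in the supervision penalty, importance 0 in RFE.
* Ties: `which.min`/`which.max` take the first optimum (RFE keeps the
  larger subset; cutoff selection takes the lower cutoff; KMeans
  assignment takes the lower cluster index).
* Rounding of reported normalized scale statistics: half-to-even, four
  decimals.
* Test problem sizes are chosen to make each statistical check sharp but
  cheap: correlation targets at $n = 2000$; screening-regime and cutoff
  recovery at the study-sized $n = 417$ over 50 seeds; blob recovery over
  100 seeds at embedding dimension 8; the sweep-size check on a 500-word
  vocabulary at embedding dimension 16; type-I calibration over 50
  generated cohorts of 120 users. These sizes are the package's own
  choices and are documented here so they can be scaled up.

## Known limitations

* The cutoff-selection policy is a documented stand-in for an unpublished
  selection rule; other reasonable policies (e.g. distance-to-corner)
  would pick similar but not identical cutoffs.
* The consensus-clustering construction (co-association + components) is
  one standard recipe among several; component chaining can merge distant
  lemmas at low thresholds.
* AdaBoost uses fixed-depth `rpart` learners; its variable importances are
  split-based and not comparable in scale to coefficient magnitudes.
* The harness fits one model per family per fold; it does not perform
  statistical model comparison, and hyperparameter grids are deliberately
  small.
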