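---
title: "Filter-ensemble feature selection for fall-risk detection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filter-ensemble feature selection for fall-risk detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fallfs)
```

## The problem

People with Multiple Sclerosis (pwMS) fall frequently, and walking
impairment is one of the main modifiable risk factors. A clinical gait
laboratory produces many complementary views of the same patient: timed
walking tests and rater-assigned disability scores (EDSS functional-system
scores and their total), instrumented walkway and wearable-sensor gait
parameters under single- and dual-task conditions, postural-sway measures,
and patient-reported walking questionnaires (MSWS-12, EMIQ). Pooling
everything yields hundreds of mixed metric/ordinal features for a cohort of
around a thousand patients, of whom only ~14% report a recent fall.

`fallfs` implements a complete retrospective fall-detection analysis for
this setting: a feature-selection ensemble built from four filter methods,
four reference classifiers evaluated under repeated stratified
cross-validation, a permutation test against random guessing, and — because
clinical gait cohorts are rarely shareable — a synthetic cohort generator
with the same multi-block structure, so every stage of the pipeline is
testable end to end.

## The synthetic cohort model

Each subject has a latent disease severity $s_i \sim \mathcal{N}(0,1)$. The
binary fall label is

$$y_i \sim \mathrm{Bernoulli}\big(\sigma(\alpha + \beta s_i)\big),$$

with $\beta = 1.5$ and $\alpha$ solved numerically so the marginal
prevalence equals the target (default 0.139, i.e. 172 fallers in 1240).
An informative feature $j$ with loading $\lambda_j$ is
$x_{ij} = \lambda_j s_i + \varepsilon_{ij}$ with unit-variance Gaussian
noise; every other feature is pure noise. Ordinal items (5-level MSWS-12,
4-level EMIQ, 6-level EDSS functional scores) are produced by cutting the
latent variable at equiprobable thresholds. This single-latent-factor form
is deliberately the simplest structure under which filter methods can
provably separate informative from noise features — the tests lean on that
property.

Design choices worth knowing:

* **Default loadings.** Nine questionnaire items (`planted_features()`:
  three EMIQ, six MSWS-12) carry loading 1.1; everything else is noise. The
  loading was fixed once, before the test suite existed, from a design
  calibration: it has to be large enough that the nine items dominate all
  four filter rankings at $n = 1240$, and a Gaussian naive Bayes on the
  nine items should score in a plausible F1 band (0.4–0.6) for imbalanced
  fall detection. $\beta = 1.5$ is part of the same calibration.
* **EDSS total.** The total score is a deterministic monotone surrogate of
  the eight functional scores: on the clinical 0-based scale,
  $\mathrm{total} = \max(v) + 0.5\,\max(0, \#\{v \ge 2\} - 1)$. This is
  *not* the certified Neurostatus algorithm (which is out of scope); it is
  a documented stand-in used consistently by the generator and the
  knowledge-based imputer, which is what makes that imputer testable.
* **Missingness.** Cells of block $b$ are masked with probability
  $\mathrm{clamp}(\mathrm{mcar}_b + \sigma(\mathrm{slope}_b\, s_i) - 0.5,\;
  0, 0.95)$ — an MCAR floor plus a centred logistic shift, so dropout
  increases with severity when the slope is positive (sensor blocks default
  to slope 1, questionnaires to 0). Zero slope reduces exactly to MCAR.
* **Block widths.** The canonical map is Basic 11, EDSS 9 (a column view of
  Basic: the eight functional scores plus the total), GAITRite 82 + 82,
  Mobility Lab gait 84 + 84, sway 32 + 32, MSWS-12 12, EMIQ 9. The pooled
  "All" data set concatenates every block except EDSS: 428 columns,
  including both sway blocks — the width arithmetic, not the narrative
  enumeration, is authoritative. Custom block maps with other names are
  allowed for reduced designs (the calibration study uses an 8-feature
  null cohort); canonical names require canonical widths.

What the generator does **not** emulate: correlated background features
(real gait parameters are strongly inter-correlated within blocks; here
non-planted features are independent noise), item-specific questionnaire
structure beyond the shared factor, fall counts or time-to-fall, and
device-specific artefacts. Passing tests therefore demonstrate that the
pipeline recovers structure *of this kind*, not that it reproduces any
particular clinical data set. One consequence is documented in the
limitations section below.

## Preprocessing

Metric features are imputed with the reference median (even counts: mean of
the two central order statistics), ordinal features with the reference mode
(ties toward the smaller code, for determinism). The EDSS block gets
knowledge-based handling: a missing total is recomputed from the functional
scores with the surrogate rule; a missing functional score with an observed
total takes the mode of that score among reference subjects with the same
total, falling back to the plain mode. Ordinal items are then treated as
quasi-metric and all features are z-scored; the scale is the population
(divide-by-$n$) standard deviation, so reference rows come out at exactly
mean 0, SD 1. Constant features are dropped with a warning.

Both imputation and standardization are fit/apply pairs: statistics are
learned on reference rows and can be applied to held-out rows. The pipeline
defaults to `fit_scope = "global"` (statistics from the full data set
before cross-validation — simple, and common in clinical ML practice)
and offers `"per_fold"` (statistics re-fitted inside each
training fold) plus `nested = TRUE` (feature selection also re-run per
fold) for leakage-free evaluation, since the global protocol is known to be
optimistically biased.

## The four filter rankers

All four are implemented from first principles and cross-checked against
brute-force oracles in the test suite.

* **Chi-square**: Pearson $\sum (O-E)^2/E$ on the feature-level × label
  table. **Information gain**: $H(y) - H(y \mid X_j)$ in bits. Both
  discretize continuous features into equal-frequency 10-bin codes
  (features with ≤ 10 distinct values — ordinal codes — are used as-is);
  equal-frequency binning is robust to the skew of gait measures, and tied
  quantiles simply collapse bins.
* **MRMR**: greedy forward selection maximizing
  $I(X_j; y) - \frac{1}{|S|}\sum_{s \in S} I(X_j; X_s)$ (the difference
  form, MID; the quotient form is available via `mrmr_form = "quotient"`).
  The reported score is the greedy objective at selection time. Because a
  rank threshold only ever consumes the top $m$ entries and the greedy
  prefix is invariant to truncation, `run_fs_ensemble` caps the greedy
  depth at $m$; the remainder is appended by relevance with `NA` scores.
* **ReliefF**: for each probe, the $k = 10$ nearest hits and misses under
  Manhattan distance on range-normalized features; the weight accumulates
  mean miss-difference minus mean hit-difference. Probes default to
  exhaustive (every instance), making the default deterministic without a
  seed. Distances are rounded to 9 decimals before neighbor ordering so
  that exact ties — common on discrete data — are broken by sample index
  regardless of floating-point summation order; this is what makes the
  ranking invariant under feature permutation.

Score ties anywhere are broken lexicographically by feature name and
logged.

## The ensemble calculus

Each ranked list is cut to its top $m = \max(1,
\mathrm{round}(\theta p))$ features, $\theta \in \{1.0, 0.5, 0.25, 0.1\}$,
rounding half away from zero — a deterministic rule whose floor of one
feature keeps even tiny data sets usable. The four filter subsets are then
combined by membership count: Union (≥ 1), Union 2 (≥ 2), Union 3 (≥ 3),
Intersection (= 4) — threshold first, combination second. Threshold 1.0 is
the no-selection baseline and ignores the combination. An empty
intersection (possible for disjoint rankings) is flagged and the
configuration recorded as infeasible rather than raising an error, since
an infeasible cell is a result in its own right.

## Classification and evaluation

Four reference families: Gaussian naive Bayes (no tuning), CART decision
tree (criterion gini/entropy, depth 2–10, minimum leaf size 5–30), kNN
(uniform/distance weights, euclidean/manhattan, $k = 2$–10) and an
RBF-kernel SVM ($C \in \{0.1, 1, 10, 100\}$,
$\gamma \in \{10^{-5}, \dots, 1\}$). Grid search uses stratified 5-fold CV
with per-fold-mean F1 (cheap and sufficient for comparing candidates); ties
go to the earliest candidate under a documented simple-to-complex
enumeration (shallower trees, larger leaves; smoother kNN; smaller $C$ and
$\gamma$).

Evaluation repeats stratified 5-fold CV 10 times (tests and the pipeline
default to fewer repetitions; the scale is a parameter, not a semantic).
Within a repetition the out-of-fold predictions are pooled and F1, recall,
precision, specificity and Cohen's kappa computed once; the report is the
mean ± SD over repetitions. Pooling per repetition (rather than averaging
fold metrics) matches the very small SDs that repeated CV produces on a
fixed data set. Zero-denominator ratios are reported as 0 with a warning.
Folds are dealt round-robin per class, so every fold's class count is
within one sample of proportionality.

The permutation test re-scores the chosen configuration on uniformly
permuted labels and reports $p = (1 + \#\{\mathrm{null} \ge
\mathrm{obs}\})/(B + 1)$. Hyperparameters are *not* re-tuned per
permutation: re-running the grid search 1000 times would be
computationally disproportionate, and reusing the chosen configuration
tests the same null (no feature–label dependency). The calibration study
(`permutation_calibration_study`) verifies the type-I error empirically on
label-independent cohorts; it uses a 35%-prevalence null cohort because at
13.9% prevalence a null naive Bayes predicts all-negative, F1 ties at 0
for every permutation, and the add-one rule collapses all p-values to 1 —
conservative, but useless for checking calibration.

The experiment pipeline (`experiment_grid` / `run_grid` / `select_best` /
`report_selection`) crosses data sets × models × ensemble configurations,
records infeasible cells as skipped, computes permutation p-values for the
per-data-set winners only, and selects winners by maximum mean F1, with
ties going to the configuration with fewer features and any residual tie
to the documented model order (GNB, DT, kNN, SVM).

## Problem sizes used by tests and the acceptance script

Oracle-equivalence checks run on ≤ 40 × ≤ 6 instances; the planting
property uses 40 cohorts of 1240 × 51; the recovery study 20 cohorts of
1240 × 428; the selection-benefit comparison 6 cohorts with 2 CV
repetitions per arm; the calibration study 50 null cohorts of 120 × 8 with
200 permutations each. These sizes were chosen so the whole suite completes
on a single CPU in well under half an hour while leaving each check
adequately powered (e.g. the calibration band is the exact 99% binomial
interval for 50 trials at level 0.05).

## Known limitations

* The generator's pure-noise background makes the *selection-vs-baseline*
  comparison conservative for F1: removing independent noise features
  barely changes (and can slightly improve) the F1 of a Gaussian naive
  Bayes at this sample size, because the extra prediction noise moves the
  default operating point toward lower recall and higher precision. The
  *recall* advantage of the selected subset — the headline pattern —
  reproduces robustly. Backgrounds with correlated severity signal flip
  the F1 direction positive but defeat MRMR-intersection recovery of the
  planted items; within the single-latent-factor family both cannot hold
  at once, and the package keeps the simple, analysable default.
* Ordinal items are treated as quasi-metric after coding, so distances and
  z-scores inherit the usual equal-spacing caveat.
* The EDSS surrogate rule is a stand-in; results involving the total score
  should not be interpreted against clinical Neurostatus scoring.
* With `fit_scope = "global"` (the default) preprocessing statistics see
  the evaluation folds;
  use `"per_fold"`/`nested` for unbiased estimates.
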