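---
title: "Mapping the Oxford Knee Score onto EQ-5D-5L: models, design and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the Oxford Knee Score onto EQ-5D-5L: models, design and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(oksmap)
```

## The problem

Cost-utility analysis needs a single preference-based index, and the
EQ-5D-5L provides one: five domains (mobility, self-care, usual
activities, pain/discomfort, anxiety/depression) at five levels each,
whose 3,125 profiles a country-specific value set converts to a utility
anchored at 1 = full health, with states worse than dead below 0. The
Oxford Knee Score — twelve items, each 0 (severe) to 4 (very mild),
total 0–48 — is what most knee-osteoarthritis studies actually collect,
and it carries no tariff. `oksmap` predicts the *responses* to the five
EQ domains from the twelve OKS items and converts the predicted profile
afterwards, so a single fitted mapping serves any tariff, present or
future. Direct regression of the utility index, by contrast, is tied to
the one tariff it was trained on and must cope with the spiked,
ceiling-heavy utility distribution.

## Model families

All four families treat each domain as an ordinal outcome; nominal
(binomial/multinomial) baselines are excluded on principle because they
discard the level ordering.

### Cumulative link models

The ordered levels are assumed to arise by thresholding a latent
continuous variable: \(P(y \le k \mid x) = G(\theta_k - x^\top\beta)\)
with strictly increasing thresholds \(\theta_1 < \dots < \theta_{K-1}\)
and inverse link \(G\). Five links are supported: logit
(\(\log\frac{p}{1-p}\)), probit (\(\Phi^{-1}\)), cauchit
(\(\tan(\pi(p-0.5))\)), cloglog (\(\ln(-\ln(1-p))\)), and logc
(\(-\ln(1-p)\)). The *parallel* variant shares one slope vector across
all thresholds (proportional odds when the link is logit); the
*non-parallel* variant gives every threshold its own slopes.

Fitting is maximum likelihood with analytic gradients (BFGS, three
jittered restarts on non-convergence). Two numerical decisions matter:

* **Crossing curves.** Non-parallel cumulative curves can cross,
  producing negative category probabilities. The likelihood clips
  category probabilities at \(\varepsilon = 10^{-10}\) (with a zero
  subgradient in the clipped region) and the fit reports a
  `crossing_detected` flag rather than failing.
* **The one-sided logc link.** \(logc\) maps \([0,1)\) to
  \([0,\infty)\); negative linear predictors are clipped to probability
  zero, and the top cumulative probability is fixed at 1 and never
  transformed. It is admitted only in the plain cumulative family.

### Penalized cumulative regression

The parallel cumulative model is penalized on its slopes — ridge
(\(\alpha=0\), sum of squares) or lasso (\(\alpha=1\), sum of absolute
values), thresholds unpenalized — over a log-spaced path of 20 penalty
magnitudes from \(\lambda_{\max}\) (the smallest magnitude shrinking
every lasso slope to zero, taken from the null-model score) down by
\(10^{-3}\). Optimization is proximal gradient (FISTA) with backtracking
and adaptive restart; the lasso proximal step is an exact
soft-threshold, so zeros are exact. Predictors are standardized
internally and coefficients reported on the original scale.

The path point is selected by AIC or BIC with model degrees of freedom =
(K−1) thresholds + the number of nonzero slopes (lasso) or the standard
ridge trace \(\sum_j d_j^2/(d_j^2 + n\lambda)\) on the standardized
design (ridge) — the nonzero count is meaningless under ridge, which
never zeroes a slope. The ridge df is the familiar linear-model
approximation, documented as such.

### Cost-sensitive ordinal CART

Scores \(s_1 < \dots < s_K\) (by default the level integers) are
assigned to the ordered levels, and nodes are split to minimize the
generalized Gini impurity
\(i(t) = \sum_{i,j} C(i,j)\, p_i p_j\) with cost
\(C(i,j) = |s_i - s_j|\) (absolute) or \((s_i - s_j)^2\) (quadratic),
so a two-level miss costs two or four times an adjacent miss. Split
candidates are midpoints of sorted unique predictor values; ordinal OKS
items enter as numeric scores 0–4.

The complexity parameter follows cost-complexity semantics throughout:
a split must improve the root-scaled impurity by at least `cp` to be
made, and the grown tree is pruned back by weakest-link pruning at the
same `cp` on the scale of the chosen pruning risk — misclassification
*rate* (all errors equal, modal-level node predictions) or
misclassification *cost* (errors weighted by \(C\), cost-minimizing
node predictions). Whether `cp` should gate impurity improvement or
cost-complexity pruning is genuinely ambiguous in the source method; the
implementation applies it to both, which is how `rpart`-style trees
behave, and exposes the pruning risk through `prune_rule`. The outer
cross-validation tunes `cp`; no separate internal cross-validation is
run. The 20 grid values are drawn log-uniformly on
\([10^{-4}, 10^{-1}]\) from the run seed — the source method states only
that 20 values were randomly selected, and this range brackets the
selected values such searches typically land on.

### Ordinal forests

Instead of fixing the level scores, the forest family searches over
them: `nsets` candidate monotone score sets are drawn as sorted uniform
variates on \([0,1]\) with anchored endpoints (first level 0, last
level 1); each candidate scores the outcome and a small regression
forest of `ntreeperdiv` trees is grown on it, judged by out-of-bag
accuracy after mapping out-of-bag score predictions back to levels at
the midpoint boundaries between adjacent scores. The best candidate
grows the final forest of `ntreefinal` trees. Ties in candidate
performance resolve to the earlier candidate; all forests are grown
single-threaded with explicit seeds, so identical seed + data +
hyperparameters give identical predictions.

The regression forests themselves are grown by `ranger`; the score-set
search, boundaries and level mapping are the package's own.

## Predictor sets

Each structure is tried with four predictor constructions, built once
per domain on the estimation sample and then held fixed — the same
workflow as identifying the sets first and selecting models second.
Validation data are always pushed through the estimation-sample
transform (centers, scales, rotation); nothing is refitted downstream.

1. **All** twelve items.
2. **RFE** — recursive feature elimination under a random forest with
   repeated stratified cross-validation (5 × 5 by default): items are
   ranked by impurity importance within each training split, nested
   subsets of every size 1–12 are scored by held-out accuracy, the best
   mean-accuracy size wins (ties toward fewer items), and the top items
   of the full-sample ranking at that size are returned.
3. **Model-based** — each family's own importance: absolute
   standardized slopes above their mean (cumulative; the cut-off is the
   package's choice, since "above the built-in importance" needs a
   threshold), nonzero slopes at the BIC-selected lasso penalty
   (penalized), positive split-gain sums (CART), impurity importance of
   the final forest (ordinal forest). An empty screen (e.g. a fully
   shrunk lasso) falls back to all items with a warning.
4. **PCA** — items centered and scaled, components from the correlation
   structure, the smallest leading set reaching 90% cumulative variance.

## Tournament, selection, refit

Every (structure, predictor set) trial — 532 per domain at the full
grid — is evaluated by repeated stratified k-fold cross-validation. The
headline geometry is 5 folds × 3 repeats; the phrase "5 × threefold"
admits both readings, so folds and repeats are plain configuration
fields and 3 × 5 is one flag away. Fold assignment is outcome-stratified
wherever level counts permit; a training split left with a single level
triggers a flagged fold merge, never a silent skip. The winner is the
accuracy argmax; exact ties break toward the simpler family (cumulative
< penalized < CART < forest), then toward fewer predictors.
Non-converged trials are excluded from ranking and logged. The winner is
refitted on the whole estimation sample.

Two computational shortcuts keep the tournament exact but fast: CART
trees are grown once per split-cost at the smallest grid `cp` and every
(cp, prune-rule) variant is derived by snipping (provably identical to
regrowing, since growth gates depth-first) plus re-pruning; and all
forest structures within a fold share one candidate-score-set pool, with
out-of-bag accuracy for smaller `ntreeperdiv` values read off leading
tree subsets of the largest forest. The AIC and BIC penalized variants
share one penalty path.

## Evaluation

Baseline accuracy is the share of the most common level; crude accuracy
the share of exact matches, with a percentile bootstrap CI (B = 2000 by
default — the CI method for accuracy is unstated in the source
tables, so the same bootstrap machinery as the utility errors is used).
Predicted domain levels are assembled into five-digit profiles, both
actual and predicted profiles converted to utilities under each value
set, and MAE/MSE reported with percentile bootstrap CIs, resampling
patients so the five domains stay coupled. The median-split MAE
stratifies at the median of the *observed* utilities by default
("estimated utility" is ambiguous between observed and model-estimated;
both are exposed via `split_on`).

Value sets come in two dialects: *additive* (per-domain per-level
decrements plus a full-health constant; main effects only) and *lookup*
(a complete 3,125-row profile-to-utility table). Tariffs with
interaction terms and crosswalk tariffs are supplied in lookup form;
the crosswalk regression between the 5L and 3L descriptive systems is
out of scope. Licensed national tariffs are not bundled; two toy sets
are, and the additive one is the package's canonical toy tariff
(utilities 1 down to −0.20, decrement steps of realistic magnitude).

## The synthetic cohort generator

No patient-level data ship with the package, so every end-to-end claim
runs on a generator designed around the structure such cohorts
exhibit: a single latent health factor \(U \sim N(0,1)\) per patient;
each OKS item observed as the bin of \(a_j U + e\) and each EQ domain as
the bin of \(b_d U + e\), \(e \sim N(0, \sigma)\), under per-item
strictly increasing thresholds — a graded-response-style model, chosen
because the cumulative family's own premise is a categorized latent
continuum. OKS loadings are positive and EQ loadings negative, so all
item-domain correlations come out negative.

Calibration of the defaults: EQ thresholds are set from the bundled
reference level counts of a knee-osteoarthritis estimation cohort
(n = 456), so expected marginal frequencies match them (e.g. self-care
level 1 ≈ 59%); OKS thresholds approximate the reference per-item means
and SDs through a discretized-normal fit; loadings (OKS ≈ 1.25–1.65, EQ
−1.8 to −0.75 with anxiety/depression weakest) put the first principal
component of the standardized items at ≈ 66% of variance and the
item-domain Spearman correlations in roughly −0.7 to −0.4 at n = 5000.
Estimation (n = 456) and validation (n = 115) cohorts share one
population model and differ only in size and seed; seeds are explicit
spec fields, never global state.

What the generator does *not* emulate: covariates (age, sex,
arthroplasty status, comorbidities), EQ-VAS, multi-factor structure,
differential item functioning — and, importantly, *cohort drift*: a real
external validation sample recruited later can be systematically
healthier than the estimation sample, which makes its below-median
utility stratum easier to fit than the one produced here, where both
cohorts are equally severe by construction. Passing tests therefore
demonstrate the machinery and its statistical behaviour under the
stated structure, not performance on any particular clinic's data.

## Problem sizes and the reduced grid

The packaged studies run at two scales, both chosen as the package's own
test conditions. The *full* profile is the complete grid (133
structures, 532 trials, 5 × 3 cross-validation). The *reduced* profile
(`run_config(reduced_grid = TRUE)`) keeps all cumulative and penalized
structures, draws 5 CART cp values instead of 20, halves the three
forest size grids, and cross-validates 3 folds × 1 repeat; it covers
all four families end-to-end at the study sample sizes (456/115) in
about six minutes on one CPU. The test suite's smoke runs thin the grid
further. Bootstrap B is 500 in the scripted runs, 2000 by default.

## Known limitations

* Ridge degrees of freedom use a linear-model trace approximation.
* The CART probability output is a degenerate one-hot surrogate; only
  level predictions are first-class for the tree family.
* Accuracy-driven selection favours majority levels; rare level-5
  responses are often predicted one level low (the tie-break toward the
  healthier level is deliberate, for reproducibility), which inflates
  utility errors precisely in the sickest stratum under tariffs with
  large level-5 decrements — visible in the median-split MAE under the
  wide-range lookup toy tariff.
* Non-parallel cumulative fits with the cauchit or logc links can be
  multimodal; restarts mitigate but do not guarantee the global optimum.
* The additive value-set dialect is main-effects only by design;
  interaction tariffs must be supplied as lookup tables.
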