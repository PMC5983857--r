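---
title: "Methods: screening and classifying omic features of drug-target clinical success"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening and classifying omic features of drug-target clinical success}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`targetscreen` asks a deceptively simple question: do measurable features of
genes and proteins differ between drug targets that succeeded in late-stage
clinical development and targets that failed there? The statistical obstacles
are what make it interesting: the sample of targets with phase III outcomes is
small (a few hundred), heavily imbalanced toward successes, and biased — drug
targets are not a random draw from the genome, and entire gene families
(GPCRs, integrins) carry historical success or failure records that can
masquerade as feature effects. This vignette records the package's model,
its conventions, and the reasoning behind the choices that the problem left
open.

## Outcome model

The unit of analysis is the *target* (a gene), not the trial. Asset-level
records are filtered to selective (single-target) assets with human targets,
non-cancer indications, and decisive phase III outcomes; each target is then
scored by its *best* outcome: one approval makes it a success, no approvals
plus at least one phase III failure makes it a failure, anything else leaves
it unlabeled. Restricting failures to phase III enriches for efficacy
failures over the safety and exposure failures that dominate earlier phases;
excluding cancer indications avoids a disease area with systematically
different target biology and failure rates. Best-outcome scoring ignores
nuance deliberately — a target that succeeded once and failed five times
counts the same as one that always succeeded — and the success rate the
summary prints is the computed ratio `n_success / (n_success + n_fail)`,
nothing else.

## Feature model and standardization

Each omics dataset is a gene × feature matrix of one of three value shapes,
and its shape governs its treatment:

* **quantitative-filled** (e.g. microarray expression): columns are z-scored
  with the *population* standard deviation. The population convention is
  what makes standardization exactly idempotent, and it matches the worked
  values the row summaries are tested against.
* **quantitative-sparse** (e.g. immunohistochemistry scores): columns are
  divided by their mean, which preserves structural zeros as absences and
  gives every column mean one.
* **categorical-sparse** (binary annotations): left untouched.

Zero-variance (filled) and zero-mean (sparse) columns cannot be standardized
and are dropped with a warning rather than silently imputed.

Two row summaries, `mean` and `stdv` (population SD again), are appended
after standardization; they carry interpretable signal such as how broadly
and how variably a gene is expressed. Expression entropy
`H = sum_i P_i log2(1/P_i)` with `P_i = E_i / sum(E_i)` is available as a
third appended feature for expression-like data; it is computed on the raw,
un-log-transformed values, errors on negative input, and returns 0 for an
all-zero row (a point mass carries no entropy, and a gene absent everywhere
is treated the same way). Finally, features with fewer than three non-zero
values among outcome-labeled targets are removed: with two or fewer informative
observations a permutation test cannot say anything that survives correction,
and such features only inflate the multiplicity burden.

## Dimensionality reduction

Association is Spearman correlation for dense data and the cosine coefficient
for sparse or binary data (rank correlation degenerates under heavy zero
ties). The matrix is squared before thresholding at `r² = 0.5`, so
anticorrelated features group together. Features are ordered by decreasing
number of correlated neighbours — ties broken by original column order, a
deterministic choice the procedure needs but the problem does not dictate —
and grouped greedily; members are judged against the *original* association
matrix rather than recomputed against running group means, so the output does
not depend on the accumulation order beyond the documented tie-break. A group
that contains the dataset `mean` summary is represented by the mean itself;
any other group is represented by the plain average of its members, labeled by
its seed. Interpretability is the point: a principal component cannot be
read off a heatmap axis, a group of named tissues can.

## Permutation screening

Every feature is tested with the same statistic — the difference between
success and failure means — because no single parametric test is appropriate
across dense, sparse, and binary features with heterogeneous distributions.
The null distribution comes from shuffling outcome labels:

* The Monte-Carlo p-value uses the add-one convention
  `p = (1 + #extreme) / (1 + n_perm)`. It never returns zero, which keeps
  downstream FDR arithmetic valid; the convention is conservative by at most
  `1/(n_perm + 1)`.
* Whenever the number of distinct labelings is at most `n_perm`, exhaustive
  enumeration silently replaces sampling and the p-value is exact. The
  within-stratum enumeration is the product of per-stratum combinations.
* One set of label permutations is drawn per screening call and shared by all
  features of the dataset. Each feature's marginal p-value is unchanged in
  distribution, the induced dependence between p-values is exactly what the
  Benjamini–Yekutieli adjustment tolerates, and the screen becomes a single
  matrix product instead of thousands of independent resampling loops.
* Equality of a permuted statistic with the observed one is judged with a
  relative tolerance of `1e-12`, so ties (common for binary features) count
  as extreme rather than being lost to floating-point noise.

BY adjustment is applied within each dataset (`stats::p.adjust`, validated
inputs), and features pass at adjusted p < 0.05. BY rather than
Benjamini–Hochberg because the features of a dataset are arbitrarily
dependent — the reduction step guarantees residual correlations up to
`r² = 0.5` survive. One practical consequence of the add-one convention worth
knowing: at 2000 permutations the smallest attainable raw p is `1/2001`, which
BY over 50 features multiplies past 0.05 — a desk-scale screen of that shape
can reject nothing, and its empirical false discovery rate is exactly zero.

The stratified variant shuffles labels only within target classes, preserving
each class's success/failure ratio in every null draw. A feature that merely
discriminates a historically lucky class from everyone else is constant
within strata and cannot reach significance; a genuine effect must hold
within several classes at once. Unclassified targets share one pooled
stratum by default: giving each its own stratum would freeze its label and
drain the test's power, while pooling treats "no recorded family" as just
another family. Targets listed under several classes take their first listed
class, since stratification needs a partition.

## Robustness schemes

Replication probability is the fraction of bootstrap rounds (default 1000)
in which a feature remains significant in a full rerun of the within-dataset
screen; a feature passes at probability > 0.8. Three schemes probe different
failure modes: the plain bootstrap varies the sample; the class-holdout
bootstrap removes outcome-correlated classes from the resampling pool
entirely (the bootstrap sample size equals the *post-exclusion* pool size —
after deciding a class may not inform the analysis, the reduced set is the
natural "original"); and the within-class-permutation bootstrap reruns the
stratified screen on each resample. Rounds with fewer than two targets of
either outcome are redrawn, with a warning if redraws exceed 10% of rounds.
Each bootstrap round reuses the configured permutation count; desk-scale runs
reduce it per call rather than changing the default.

Class-level tests use the same permutation machinery on binary membership
vectors (BY across classes as one family), and class–feature association
tests reuse it once more with membership as the grouping variable (BY across
all pairs). Reusing one well-tested statistic everywhere was preferred over
introducing a second test family the analysis would then have to reconcile.

## Nested cross-validation classifier

The outer loop repeats outcome-stratified 5-fold splitting 200 times (1000
train-test cycles); stratification is not optional here, because with ~20%
failures an unstratified fold can easily lose one class entirely. Within a
cycle, strictly on training targets:

1. univariate stratified screening per dataset (10⁴ permutations; strict mode
   keeps BY-adjusted p < 0.05, the weak variant keeps nominal p < 0.05);
2. aggregation: non-human datasets and datasets under 2000 genes are
   excluded (their coverage holes would shrink the complete-case target set),
   low-coverage fallback datasets are used only when nothing else survived;
   min–max scaling is *fitted on training targets only* — scaling on all
   targets would leak test information — and cross-dataset redundancy is
   removed by cosine grouping at r² = 0.5, keeping per group the feature
   with the smallest training p (ties: larger absolute observed difference);
3. incremental elimination: both model types are evaluated by inner 5-fold ×
   20-repetition CV, the feature with the lowest mean random-forest impurity
   importance is dropped (ties: the later column), down to one feature;
4. the parsimony rule picks the fewest-feature model within 95% of both the
   maximum inner AUROC and AUPR, preferring logistic regression — the
   preference encodes interpretability, not expected performance;
5. the winner is refit on all training targets and predicts the held-out fold
   and all unlabeled targets.

Class imbalance is handled by weighting training examples inversely to class
size (logistic regression via prior weights in `stats::glm`; random forest
via class priors in `randomForest`). The forest size (default 200 trees) and
the unpenalized logistic fit are package defaults recorded in the
configuration object — nothing in the problem fixes them, and the feature
matrices reaching the models are small enough (a handful of columns) that
regularization would mostly re-solve a problem the univariate screen already
solved. A cycle in which no dataset yields a significant feature records a
null model rather than failing.

## Evaluation conventions

Out-of-fold predictions are pooled per repetition (every labeled target has
exactly one), and confusion statistics use a probability threshold of 0.5 —
the natural operating point after class-weighted training, and configurable.
Unlabeled targets receive up to five predictions per repetition and are
averaged to one. Probabilities are clipped to `[1e-6, 1 - 1e-6]` before
log-odds so the Gaussian-kernel KDE (Silverman bandwidth, `bw.nrd0`) sees
finite values; the probability-scale density applies the change of variables
`pdf(x) = pdf(y)/(x(1-x))`. Cutoff scans walk the grid of observed predicted
probabilities; PPV ties resolve toward the cutoff classifying more targets
positive and NPV ties toward more negative, so the scan prefers claims about
larger target sets. Pairwise consistency uses strict inequality — two
identical prediction vectors are 0% consistent in both directions, not 50% —
and reports qualifying ordered-pair counts at 0.95/0.99 consistency under
both separation rules (median difference at least 0.1, or at least 2-fold).

## What the synthetic generator emulates — and what it does not

The generator's default configuration reproduces the study conditions the
pipeline was built for: 259 successes, 72 failures, a 62/70 success-enriched
GPCR-like class, a 3/3 failure-pure integrin-like class, one dense
tissue-expression atlas, one sparse evidence-score dataset, one binary
annotation dataset, and planted effects of one pooled-SD unit on the
expression atlas's row mean (successes lower) and row SD (successes higher).
Unlabeled targets (669 by default, giving a round thousand-target universe at
a scale desk machines handle comfortably) are generated explicitly, and some
class members are deliberately left unclassified to exercise stratification
edge cases.

Structural choices worth knowing:

* Dense values are Gaussian around per-feature means; sparse values are
  zero-inflated lognormal; binary values are Bernoulli — matching the three
  value shapes the standardization rules exist for. All three are driven by
  one latent Gaussian copula so correlated blocks survive the sparse
  transforms.
* The expression atlas includes a right-skewed per-gene baseline
  (`row_effect = 0.85` of latent variance) and lognormal per-gene noise
  scales. This is what makes tissue columns collapse into a single `[mean]`
  group during reduction — real atlases behave exactly this way, reducing
  dozens of tissue features to a mean-expression group plus a variance
  feature — and what keeps the min–max-scaled mean and stdv features from
  being spuriously merged by the cosine step (symmetric dense features
  concentrate near the middle of the unit interval, where cosine similarity
  saturates; skewed ones do not).
* Planted effects are applied additively on the raw (pre-standardization)
  scale, so the standardization code is exercised honestly; dense values are
  clamped at zero afterwards, as intensity data would be. Row-mean effects
  shift whole gene rows; row-SD effects scale a row's deviations around its
  mean; effects on sparse features spread the shift over non-zero entries so
  absences stay absent. Row-summary effects on binary datasets are rejected
  as configuration errors.
* Asset tables are generated to reproduce the planted labels after filtering
  and scoring *and* to contain decoys (multi-target assets, cancer
  indications, non-human targets, pre-phase-III failures) that the filters
  must remove — the outcome module is tested against the generator, not just
  against hand fixtures.

What the generator does **not** emulate: indication-level structure (one
outcome per target, not per target–indication pair), missing-not-at-random
coverage, inter-dataset correlation of the same underlying biology (two
simulated atlases are independent draws, where two real atlases would agree),
and real effect sizes — the planted one-SD effects are an order of magnitude
stronger than anything a real outcome screen should expect, which is the
right regime for testing recovery machinery but means passing tests say
nothing about the power of the pipeline on real data.

## Problem sizes in the test suite

The shipped tests and the acceptance script scale the study down so the whole
suite runs in minutes on one CPU: screens use 10²–10⁴ permutations instead of
10⁵, bootstraps use 40–200 rounds instead of 1000, and cross-validation runs
use 2–10 outer repetitions (the 1000-cycle structural check uses the full
5 × 200 geometry with two-fold single-repetition inner settings). These are
run-size choices only; every default in the package remains at full scale.

## Known limitations

* The pipeline tests features one at a time before modeling; combinations of
  individually insignificant features are invisible to the strict path (the
  weak univariate mode exists precisely to probe this, and inflates the
  feature count it hands to elimination).
* Stratification controls for target class only. Disease class, modality,
  and direction of modulation are real confounders the data model does not
  carry.
* Replication probabilities inherit the granularity of their permutation
  count; with few permutations the within-round BY threshold is effectively
  unreachable and probabilities collapse toward zero (see the add-one note
  above).
* The classifier's probability outputs are not calibrated; they order
  targets well before they estimate risks well, which is why the evaluation
  module leans on ranking statistics, cutoff scans, and pairwise consistency
  rather than raw probabilities.
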