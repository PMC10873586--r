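---
title: "cellstack: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cellstack: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cellstack` treats cell-type annotation as supervised multi-class
classification: a labeled reference scRNA-seq matrix trains a two-layer
stacking ensemble which then assigns one of the reference types to every
query cell. This vignette records the model, the parameters that matter,
and the design decisions taken where the method leaves room — in enough
detail that an independent implementation could reproduce ours.

## The model

**Layer 0 — normalization.** Each cell's expression vector is divided by
its total and multiplied by `target_scale`, then log1p-transformed.
`target_scale` defaults to 1e4, the conventional counts-per-ten-thousand
target in single-cell work; it is configurable because conventions
differ by an order of magnitude across pipelines. Normalization is
strictly per cell — no statistic is shared between training and test
data, so the two are always processed independently.

**Layer 1a — one-vs-rest χ² signatures.** For each of the *t* cell types
the labels are binarized and every gene scored with a frequency-based χ²
over class-wise value sums: with observed sums
$O_c = \sum_{i: y_i=c} x_{ij}$, class counts $N_c$, gene total $T_j$ and
expectation $E_c = T_j N_c / n$,

$$\chi^2_j = \sum_{c \in \{0,1\}} \frac{(O_c - E_c)^2}{E_c},$$

with the convention that all-zero genes score 0. This is the statistic
computed by the standard machine-learning feature selectors for
non-negative features (it is linear in a per-gene scaling, not the
contingency-table χ² on detection counts); we document it explicitly
because "χ² selection" is ambiguous without the formula. Scores are
computed on the *normalized, log1p-transformed* values: selection sits
after normalization in the pipeline and log1p keeps values non-negative,
so the statistic's precondition holds. The top `k` genes per type
(default `k = 300`, configurable 10–2000) form the signature $f_k$;
ties are broken by lexicographic gene id (C locale) so the selection is
identical across platforms. Signatures may overlap between types and are
not de-duplicated — overlapping one-vs-rest problems legitimately share
discriminative genes, and on strongly structured data the per-type lists
collapse onto largely the same marker set.

**Layer 1b — out-of-fold probability features.** Each signature
sub-matrix is transformed by each of *L* base learners under a
stratified `folds`-fold scheme (default 3): the learner trained on the
other folds emits *t* class probabilities for the held-out fold. Every
cell therefore receives exactly one probability vector from a model that
never saw it, which is what prevents the meta-learner from fitting to
leaked base-learner memorization. Folds are stratified by cell type;
plain random folds can starve a rare type out of a training split
entirely, and stratification matches the evaluation protocol's own
stratified cross-validation. A class with fewer cells than `folds` is a
hard error with a remediation hint (reduce the folds or drop the class):
silently shrinking the fold count would change the method.

The blocks are concatenated with the outer loop over cell types in
codebook (lexicographic) order, the inner loop over learners in declared
order, and the *t* class probabilities innermost, also in codebook
order. The resulting meta matrix is *n* × (*t·L·t*) — *n* × (*t* × 2*t*)
for the default learner pair — and the fixed column order makes
serialized models portable.

**Layer 2 — meta-classifier.** A multinomial L2 (ridge) logistic
regression on the meta features. After the meta-learner is trained on
out-of-fold features, each base learner is refit on its full
sub-dataset; those refit models produce the meta features for new data
at prediction time. The refit is the standard stacking-cross-validation
protocol: out-of-fold features exist to train the meta-learner honestly,
while prediction should use base learners trained on all available
reference cells.

**Prediction.** The query is normalized with the model's stored
settings, aligned onto the model's signature gene space (missing genes
zero-filled with a warning, extra genes dropped; fully disjoint gene
spaces are an error), transformed by the refit base learners, and
classified by the meta-learner; the predicted type is the arg-max of the
meta probabilities with ties broken by codebook order. A query cell of a
type absent from the reference is necessarily assigned some reference
type — the model has no novel-type rejection; this is a documented
limitation, not a failure mode we attempt to paper over.

## Base learners and hyperparameters

The method prescribes which learners to stack but not their
hyperparameters; our defaults are the field-standard ones and all are
overridable through `base_learner(params = ...)`.

| learner | implementation | defaults |
|---|---|---|
| `svm` | RBF-kernel SVM, e1071/libsvm | `cost = 1`, `gamma = 1/(m · var(x))`, Platt-calibrated probabilities via pairwise coupling |
| `lr` | multinomial ridge LR, glmnet | `C = 1` mapped to `lambda = 1/(n·C)`, no standardization |
| `rf` | probability forest, ranger | 500 trees |
| `gbc` | gradient boosting, xgboost | 100 rounds, `eta = 0.1`, depth 3 |
| `mlp` | softmax perceptron, nnet | 50 hidden units, decay 1e-4 |

The SVM's probability calibration uses internal cross-validation and is
therefore seeded; every random draw in the package (fold assignment,
learner fitting) derives deterministically from the single model seed,
so two fits with the same seed are bit-identical, and a saved model
predicts identically after reloading. The meta-learner is the same ridge
logistic regression with its own `meta_C` (default 1).

The ensemble is *dynamic* in the sense that the first layer contains
`t × L` models: more cell types automatically mean more base models, and
`rf`/`gbc`/`mlp` can be appended to (or substituted for) the default
pair when a larger ensemble is wanted; cross-species transfer in
particular can favor the MLP variant.

## Evaluation conventions

* Accuracy is the fraction of correctly assigned cells. Per-class F1 is
  `2TP/(2TP+FP+FN)` with the zero-division convention F1 = 0 (a present
  but never-predicted class scores 0 rather than NA). Macro F1 is the
  unweighted mean, median F1 the median (mean of the middle two for an
  even class count).
* Per-class F1 is computed over the classes present in the **test
  truth**. In cross-species settings the reference may contain types the
  query lacks and vice versa; scoring the truth's classes means
  query-only types (which the model cannot predict) count as F1 = 0,
  while reference-only types contribute prediction columns to the
  confusion matrix but no F1 term. The confusion matrix is dimensioned
  over the sorted union of true and predicted labels.
* The intra-dataset protocol is stratified k-fold cross-validation
  (default 5) in which *feature selection is refit inside every fold* —
  selecting signatures on the full data before splitting would leak
  label information into the held-out folds.
* Pooling several training datasets (the inter-dataset protocol) uses
  the intersection of their gene spaces: a union would require imputing
  unmeasured genes inside training data.
* Class-balanced down-sampling reduces every class above a per-class
  `target` to exactly `target` cells, sampled without replacement,
  keeping smaller classes whole and preserving cell order. The repeated
  protocol (default 5 rounds) derives round *r*'s sampling seed as
  `seed + r` while holding the model seed fixed, so rounds differ
  exactly through the sampled training set; the reported metrics are
  arithmetic means over rounds and the per-round reports are retained.
  Down-sampling cannot help when the rarest class is itself too small —
  the target is bounded below by the smallest class one is willing to
  keep whole.

## The simulator, and what passing tests do not show

`simulate_dataset()` draws counts from a negative binomial
(`size = 1/dispersion`, so variance `mu + dispersion·mu²`) with a
disjoint block of `markers_per_type` genes per type whose means are
multiplied by `exp(log_fold_change)` in their own type, and an optional
per-batch per-gene log-normal factor (`batch_effect_sd` on the log
scale). Defaults — 3 types × 200 cells, 1000 genes, 10 markers/type,
log-fold-change 2, base mean 5, dispersion 0.3, no batch effect — are
the reference conditions used throughout the test suite and the
acceptance script: a clearly separable but noisy and over-dispersed
problem.

The simulator deliberately omits several features of real scRNA-seq
data: zero-inflation beyond what the negative binomial produces,
library-size variation across cells, protocol- or chemistry-specific
effects, correlated gene modules, and continuous or ambiguous cell
states. Passing tests therefore demonstrate that the machinery is
correct (selection finds planted signal, stacking does not leak, metrics
and protocols do what they claim) — not that any particular accuracy
will be attained on real tissues. `simulate_pair()` provides the two
cross-dataset fixtures: a batch-shifted pair (same types, different
batch factors) and a label-subset pair in which the test set carries one
extra type absent from training.

## Numerical and degenerate-input choices

* All-zero cells are an error by default (they usually indicate a broken
  upstream filter); `drop_empty_cells = TRUE` drops them with a warning
  naming the count.
* Gene/cell identifier collisions are errors, never silently
  de-duplicated — merged identifiers would corrupt signatures.
* Ridge logistic fits on a single-gene sub-matrix pad a zero column
  (the solver requires two predictors); the pad is inert.
* The lambda path passed to the ridge solver descends to the target
  lambda from 100× above it, which stabilizes the fit relative to a
  single-value path; predictions are taken at the target lambda.
* Probability blocks are renormalized to row-sum 1 before assembly,
  guarding against solver round-off; the test suite asserts row sums to
  ±1e-6.
* Dense input files default to cells-in-rows, matching the *n* × *m*
  convention; a flag flips the orientation. The Matrix Market reader
  follows the 10x genes × cells convention and transposes on read.

## Problem sizes

The test suite and acceptance script run entirely on simulated data
sized for a single CPU: the reference simulation is 600 cells × 1000
genes; meta-geometry checks sweep t ∈ {2,3,4,6} and L ∈ {1,2,4} at 18
cells per type; the down-sampling size check uses the 6009/1333/4792
imbalance at 8 genes (only class counts matter there); cross-validated
end-to-end runs use k = 50 genes per type, which the signature-sweep
literature places well inside the flat region of the
performance-vs-k curve for separable data.

## Known limitations

* No novel-type detection: every query cell receives a reference type.
* No batch-effect correction is applied; cross-batch robustness comes
  from the signature + stacking construction alone.
* Severe reference imbalance degrades minority-class F1; the down-
  sampling protocol mitigates but cannot fix a too-small rarest class.
* The χ² statistic scores each gene marginally; co-expressed marker
  modules are selected redundantly rather than complementarily.
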