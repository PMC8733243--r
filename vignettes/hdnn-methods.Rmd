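---
title: "Hybrid neural-network decision trees for imbalanced pre-miRNA classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid neural-network decision trees: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdnnmir)
```

## The model

`hdnnmir` classifies candidate hairpin sequences — described by a fixed
vector of numeric features, conventionally 29 of them — into true
precursor-miRNAs (label 1) and pseudo-hairpins (label 0). The central
difficulty is class imbalance: realistic screens contain one positive per
hundreds to thousands of negatives, and a monolithic classifier trained
with an unweighted loss drifts toward predicting the majority class.

The hybrid model (H-DNN) is a binary decision tree in which every internal
node holds a small dense feed-forward network. Growth is recursive:

1. Train a network on the samples reaching the node (fresh initialization,
   seed derived from the node id; mini-batch gradient descent on softmax
   cross-entropy).
2. Route every sample through the trained network; the two output units
   give scores $y = (y_0, y_1)$ and the sample goes to the left child when
   $\arg\max_k y_k = 0$, right otherwise. Ties break to the lower index.
3. Score the induced partition by the weighted Gini impurity
   $\frac{n_L}{n} G_L + \frac{n_R}{n} G_R$ with
   $G = 1 - \sum_j p_j^2$, and accept the split only if it improves on the
   parent's impurity by at least `min_impurity_decrease` and the
   depth/size bounds allow it. Rejected nodes become leaves labeled with
   their majority class.

The tree confines each network to an ever-purer subproblem: even when a
root-level network under an unweighted loss leans toward the majority
class, any split with positive impurity decrease concentrates positives in
one branch, and the child networks retrain on those easier conditionals.
Prediction routes a sample root-to-leaf through the same argmax rule
(inference mode, no dropout) and returns the leaf label; it is fully
deterministic.

Child nodes re-learn from the original feature vectors of their samples,
not from the parent network's hidden activations. The alternative —
feeding hidden-layer outputs to children — would entangle every node's
input space with its ancestors' training trajectories; re-learning from raw
features keeps nodes exchangeable and the model serializable node by node.

### The node network

Layers are dense. Hidden layers use ReLU, the 2-unit output layer is
linear; softmax enters only through the loss, and the argmax routing is
invariant to it, so scores may be read either way. Per-unit activation
thresholds are absorbed into the biases. The reference topology is
`input → 512 → 256 → 64 → 32 → 16 → 2` with dropout after the 256- and
16-unit layers; every width is configurable through `network_spec()`, and
the test suite and examples use much narrower nets (8–32 units) because the
synthetic problems they solve do not need the capacity.

Training is plain mini-batch gradient descent. The output-layer error
signal is $\delta = \mathrm{softmax}(z) - y_\text{onehot}$, which is the
exact gradient of softmax cross-entropy; weight gradients are
$\frac{1}{m}\Delta + \lambda w$ with the L2 term never applied to biases.
No momentum or adaptive optimizer is used: the per-node problems are small
and the point of the architecture is that shallow training per node
suffices.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| `epochs` | 2 | The node networks reach a usable true-positive rate within two passes; longer training overfits the tiny positive class at high imbalance. |
| `batch_size` | 32 | Small enough that minority samples influence many updates per epoch. |
| `learning_rate` | 0.01 | Conservative default for unit-variance features; the examples use 0.05–0.2 on easy synthetic problems. |
| `lambda` | 0 | L2 on weights only; off unless the feature count is large relative to node size. |
| `dropout_rate` | 0.2 | Applied (inverted) after the 256- and 16-unit layers in training mode only. |
| `max_depth` | 5 | With argmax routing each level can isolate one mode of each class; 5 levels cover the benchmark ladders' subproblem sizes. |
| `min_samples_split` | 20 | Below ~20 samples a fresh network cannot be trained meaningfully. |
| `min_impurity_decrease` | 1e-4 | Accepts any genuinely impurity-reducing split while rejecting numerically neutral reshuffles. |
| `test_fraction` | 0.3 | Stratified 70/30 split; stratification is mandatory at IR 1:5000 or the test set may contain zero positives. |

The stopping criteria and the split protocol are repository conventions:
the growth procedure as classically printed initializes its acceptance
threshold at zero impurity and can therefore never fire; this package
adopts the only reading consistent with using Gini as a split cost —
track the weighted child impurity and accept impurity-*decreasing* splits.

## Imbalance-ratio subsampling

`target_counts()` implements the deterministic rule that generates the
benchmark count ladders. Primary rule: keep all negatives and retain
`round_half_up(n_neg / k)` positives. If the dataset holds fewer positives
than that (low ratios, or the tiny virus collection), the fallback keeps
all positives and subsamples negatives to `n_pos × k`, capped at the
available negatives. Rounding is half-up to the nearest integer — the only
rounding consistent with every printed ladder cell (218,154 / 3,000 =
72.718 → 73, where floor would give 72; 28,359 / 5,000 = 5.6718 → 6).
Which rows are kept is a uniform draw without replacement under an explicit
seed; independent draws per ratio, not nested subsets (nesting is an
alternative the source material does not determine; independence is the
simpler convention).

The shipped manifests record the five benchmark collections' sizes. The
plant positive total is 2,172: the 1:1 ladder row and the stated grand
total (117,101 − 114,929) agree on 2,172 against a stray in-text 2,154,
and the consistent value is used.

## Feature screening

- `correlation_matrix()`: Pearson correlations via `stats::cor`; constant
  columns are flagged with 0 rows/columns (with a warning) instead of NaN
  so the matrix stays displayable.
- `select_k_best()`: per-feature one-way ANOVA F between the two label
  groups (`stats::oneway.test`, equal variances), selecting features with
  score ≥ the mean score. The `≥` matters: an all-equal score vector
  selects everything rather than nothing. F statistics are invariant to
  per-feature affine rescaling, so the mask is scale-free.
- `rfe_cv()`: recursive elimination, one feature per iteration, importance
  = mean absolute coefficient of a ridge-penalized logistic regression
  (`glmnet`, α = 0, fixed λ = 0.1, standardized) across stratified CV
  folds (default 5). The elimination order maps to scores in [0, 1]
  (0 = first out, 1 = last survivor). A ridge-linear base learner is the
  smallest-assumption choice for numeric features with binary labels; the
  learner and fold seed are recorded in the report for auditability.
- The two masks combine with AND by default (`preprocess_report()`);
  on well-separated data both selectors tend to keep the informative set,
  and either mask can be used alone via `combine`.

## Evaluation conventions

Sensitivity is positive-class recall, specificity negative-class recall.
F1 and precision are **macro-averaged** with the 0/0 → 0 convention for
undefined per-class precision. This is the convention under which an
all-negative classifier on a heavily imbalanced test set reports
F1 = Prec = 0.50 (the negative class contributes ≈ 1, the missed positive
class 0) — the signature of the degenerate rows in published benchmark
tables, which binary-positive F1 (which would give 0) cannot produce.

`ir_sweep()` runs subsample → stratified split → grow → held-out metrics
per ladder ratio and returns a tidy one-row-per-ratio data frame; ratios
whose target counts leave no positive on either side of the split are
recorded as skipped rather than failing the sweep.

## The synthetic generator

`generate_feature_table()` draws negatives from a zero-mean equicorrelated
Gaussian (`x = sqrt(ρ)·z₀ + sqrt(1−ρ)·z`, unit marginal variance) and
shifts the first `n_informative` features of positives by `effect_size`
standard deviations; rows are returned in a seeded permutation. It
emulates the *shape* of the benchmark tables — 29 numeric features, two
classes, imbalance up to 1:5000, tunable separation and collinearity — and
nothing else: real hairpin features are bounded, skewed, multimodal and
dependent in ways no equicorrelated Gaussian is. Passing tests on this
generator therefore demonstrate that the machinery is correct (counts,
routing, gradients, metrics, determinism) and that the hybrid recovers
signal that is present; they say nothing about accuracy on real genome
data, which is out of scope here.

## Numerical choices and degenerate inputs

- Weights initialize from N(0, 1/fan-in), biases at zero; deterministic
  per seed. All randomness flows from one top-level seed through a string
  hash (`seed, stage-name → derived seed`), keeping every derived seed a
  valid 32-bit integer.
- Inverted dropout (masks scaled by 1/(1−rate) at train time) so inference
  needs no rescaling; with rate 0 train and inference passes coincide
  exactly.
- Argmax ties route to the lower class index (negative), and leaf-label
  ties go to the negative class — the majority class overall, the
  conservative choice under imbalance.
- A single-class input to `grow_tree()` returns a depth-0 single-leaf
  model rather than an error; a routing that sends all samples one way
  rejects the split.
- Feature tables reject NaN/Inf at construction; CSV round trips write 17
  significant digits so read-back is bit-exact.
- Gini values are compared against brute-force recomputation at 1e-14:
  the vectorized and scalar forms differ in the final ulp.

## Problem sizes

The test suite runs on generated tables of 40–10,100 samples with 1–29
features; the gradient check uses 100 random networks of ≤ 3 layers and
≤ 5 units per layer against central finite differences at relative 1e-5
(avoiding ReLU-kink neighbourhoods, where the loss is not differentiable
and finite differences are meaningless); the separability benchmark uses
10,100 samples at IR 1:100 with 6-SD separation, on which the hybrid's
held-out macro-F1 is required to reach 0.90 and at least match a single
network trained with the same budget. These sizes exercise every code path
while keeping the default suite fast.

## Known limitations

- Binary labels only; no probabilistic/soft routing, no pruning, no
  ensembling.
- Feature extraction from RNA sequence is out of scope: inputs are numeric
  tables.
- Plain gradient descent can leave a node network in a dead-ReLU basin at
  unlucky seeds and very small budgets; the tree then (correctly) declines
  the split and the node becomes a leaf. Larger budgets or a different
  node seed resolve it; an adaptive optimizer is deliberately not included.
- The published per-dataset accuracy tables for the genome collections
  rest on data not distributed with their source and are not reproduced
  here; the package's claims are confined to what its tests and the
  acceptance script compute on synthetic data and on the count ladders.
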