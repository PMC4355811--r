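---
title: "Evolved fusion ensembles for small-sample expression data: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolved fusion ensembles for small-sample expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpes)
```

## The problem

Expression studies routinely measure thousands of genes on a few dozen
samples. In that regime the bias–variance trade-off is dominated by
variance: a single flexible classifier will fit the training set and
generalise poorly, and an independent validation set of useful size is
unaffordable. Ensembles help, but only when the members are both accurate
and diverse, and the usual fixed fusion rules (plain majority vote, weighted
averaging) leave the *structure* of the combination — which classifiers are
grouped, and how their votes interact — unexplored.

`gpes` treats that structure as the object of search. Base classifiers are
deliberately small, cheap decision trees made diverse at three levels
(samples, features, and fusion); genetic programming then evolves *fusion
trees* over their votes, and a greedy committee search picks the final
ensemble. This vignette records the model, the tunable parameters, the
numerical conventions, and the design decisions that were genuinely open.

## Model and training procedure

### Vote algebra

Binary labels are coded −1/+1 internally (class id 1 is mapped to +1). A GP
individual is a ternary syntax tree: leaves reference base classifiers,
internal nodes carry one of three fusion operators acting on hard votes:

* `Min` outputs −1 as soon as any child outputs −1 — a veto toward the
  negative class;
* `Max` is its mirror image, vetoing toward the positive class;
* `Average` is the majority of its three children (with three odd votes the
  mean is never zero, so no tie rule is needed).

All votes are unweighted: with so few training samples, accuracy-weighted
votes would be fitted to noise. `Min` and `Max` are literally the minimum
and maximum of the child outputs in {−1,+1}; the test suite checks all three
operators against exhaustive 8-pattern truth tables.

Every nonterminal has exactly three children and the tree depth is capped at
3 (root = depth 1), so an individual fuses between 3 and 9 leaf slots. The
cap keeps individuals interpretable and evaluation cheap; it also bounds the
search space so a population of 80 can cover it usefully.

### Base classifiers

Each terminal is a CART tree (`rpart`, Gini impurity) grown to purity
(`minsplit = 2`, `minbucket = 1`, `cp = 0`): with approximately five
features and two or three dozen training samples, fully grown trees are the
behaviour of the common library default this package mirrors, and their
instability is a feature — it is what makes the ensemble diverse. Diversity
is injected at:

* **sample level** — each tree trains on a fresh *balanced subsample*:
  all `Ns = min(N1, N2)` samples of the smaller class plus `Ns` drawn
  without replacement from the larger. Sampling without replacement (rather
  than bootstrap) matters because with tens of samples a bootstrap draw
  contains too few distinct points; the balancing also counters the class
  imbalance typical of clinical designs (e.g. 134 vs 15).
* **feature level** — a candidate pool is built as the deduplicated union of
  the top-50 genes of four selectors (ANOVA F-test; kernelised Relief with
  kernel width σ = 2; random-forest Gini importance summed over 10 trees;
  linear SVM-RFE with C = 1 removing 2 features per iteration). Four
  selectors with different inductive assumptions give the pool between 50
  and 200 genes. Each tree then sees a random subspace whose size is a
  Gaussian(5, 3) draw, rounded half-away-from-zero and clipped to
  [1, pool size].
* **classifier level** — the fusion operators themselves: two individuals
  over the same terminals with different operator structure are different
  classifiers.

### The five phases

Overfitting the validation data used for selection is the central danger, so
the training set is split by 3-fold stratified cross-validation into folds
A, B, C, giving two train/validation splits used by different phases
(`train1 = A∪B`, `val1 = C`; `train2 = A∪C`, `val2 = B`; the mapping is
configurable — any assignment with disjoint validation sets satisfies the
design):

1. **Candidate generation** — 300 trees on `train1`, votes cached on `val1`.
2. **Candidate filtering** — keep trees with strictly above-average `val1`
   accuracy; these are the GP terminals. Strictness matters: with "≥" a
   candidate set of identical mediocre trees would pass unfiltered; the
   all-equal case instead falls back to keeping everything.
3. **Evolution** — ramped half-and-half initialisation over depths 2–3
   (half "full" trees with leaves exactly at the target depth, half "grow"
   trees drawn freely below the root), 80 individuals, 200 generations,
   crossover rate 0.8, mutation rate 0.4, fitness = accuracy on `val1`
   computed from the cached votes (no tree is ever refitted inside the GP
   loop, which is what makes 16 000 evaluations affordable).
4. **Individual filtering** — the final generation is re-scored on the
   second split and filtered by the same strict above-average rule. By
   default the terminal trees are first *refitted* on balanced subsamples of
   `train2` (see Design decisions).
5. **Forward search** — the committee starts with the best individual; each
   step evaluates every unordered pair of remaining individuals and adds the
   pair whose inclusion gives the lowest majority-voting error (MVE) on
   `val2`. Adding pairs keeps the committee odd. A step that leaves MVE
   unchanged is *accepted*; only a strictly worse MVE (or exhaustion) stops
   the search. This stopping rule is deliberate variance reduction: with
   small validation sets the first MVE plateau is reached after one or two
   pairs, and stopping there would return a low-bias, high-variance
   committee; absorbing equal-MVE pairs lets committee size adapt to how
   many competent individuals exist.

### Multiclass problems

The fusion operators are only meaningful on ±1 votes, so c-class problems
are decomposed: one-vs-one (`c(c−1)/2` subproblems on the pairwise sample
subsets) or one-vs-rest (`c` subproblems on all samples). Feature pools,
candidate trees, GP runs and committees are built independently per
subproblem — sharing them would couple the subproblems' errors. Decoding is
by vote tally: OVO by argmax of pairwise wins (ties to the smallest class
id), OVR by the unique positive vote, falling back to the largest committee
vote margin (the signed sum of member votes) among positive voters, then
among all classes. Any monotone decoding rule would be admissible; this one
is deterministic and uses only quantities the committees already produce.

OVR inherits a known weakness from the balanced subsampling: for a class of
size 4 in a 6-class problem, the "rest" side of its training set is also cut
to 4 samples, which cannot even represent each remaining class once. The
package reports this behaviour as-is rather than patching it with a
different sampler.

### Metrics

Binary reports use accuracy and the two-point AUC
`(TP/(TP+FN) + TN/(TN+FP))/2` — the balanced accuracy, which is the
appropriate AUC form for a committee that outputs hard labels (there is no
score to sweep a threshold over). Multiclass reports use the micro-averaged
F-score (β = 1) and the average per-class accuracy, the mean over classes of
the one-vs-rest binary accuracy. Two identities are worth knowing and are
asserted in the tests: for single-label predictions micro precision = micro
recall = accuracy, and average per-class accuracy equals
`1 − 2(1 − accuracy)/c` — for `c = 2` it *is* accuracy, and for `c > 2` it
is never below it; its value is in comparisons between classifiers on the
same task, where sacrificing a hard class costs each of that class's errors
twice.

## Tunable parameters

| parameter | default | meaning, and why this value |
|---|---|---|
| `n_candidates` | 300 | candidate trees in Phase 1; large enough that above-average filtering leaves a terminal set in the low hundreds |
| `k_per_method` | 50 | genes per selector; four selectors give a pool in [50, 200] |
| `nf_mean`, `nf_sd` | 5, 3 | Gaussian subspace size; ~5 features per tree keeps trees tiny and decorrelated |
| `pop_size` | 80 | GP population |
| `generations` | 200 | GP generations; fitness uses cached votes so cost is modest |
| `crossover_rate` | 0.8 | probability a selected pair undergoes subtree crossover |
| `mutation_rate` | 0.4 | per-individual probability of one point mutation |
| `relief_sigma` | 2 | Relief kernel width (distance units of standardized features) |
| `rfe_step` | 2 | features removed per SVM-RFE iteration |
| `rf_n_trees` | 10 | trees behind the random-forest importance |
| `n_folds` | 3 | stratified folds for the phase split |

`fitness_cv = "10fold"` replaces holdout fitness with the mean per-fold
accuracy over a stratified 10-fold split of the pooled `train1 + val1`
votes — provided because both conventions are defensible for tiny samples;
the holdout default keeps fitness data disjoint from the terminals' training
data.

## Numerical conventions and degenerate inputs

* **Standardization** uses the population (divisor-`n`) standard deviation,
  floored at `1e-12`; constant features map to exactly 0. Test data is
  always transformed with the training-set statistics.
* **Ranking ties** in feature selection break by ascending feature index
  (stable, reproducible); SVM-RFE removes the tied feature with the larger
  index first.
* **Gaussian subspace sizes** round half-away-from-zero and clip to
  [1, pool size]; clipping at 1 biases the realised mean slightly above 5
  (about +0.06 at pool sizes ≥ 50).
* **Crossover depth repair**: offspring exceeding depth 3 trigger up to 10
  re-draws of the crossover points, then fall back to unchanged parent
  copies — constraint handling by rejection, never by truncation, so the
  operator never silently deletes genetic material.
* **Duplicate terminals** within one individual are allowed; forbidding them
  would complicate crossover for no measurable gain, and `Average` over
  three copies of one tree is simply that tree.
* **Degenerate inputs rejected with errors**: classes with fewer than 2
  samples, single-class label vectors, missing values (no imputation),
  feature-count mismatches at prediction time, even committee sizes.

## The synthetic-data generator

`synthetic_spec()` / `make_dataset()` emulate the regime the method is
designed for: a few thousand independent Gaussian noise genes, tens of
samples per class, and a small informative subset whose class means are
shifted by ±`shift` noise-sds in class-specific sign patterns (any two
classes differ on at least half of the informative genes). Optional latent
factor blocks add within-block correlation. `make_vote_matrix()` generates
±1 vote matrices with known per-classifier error rates for testing the
fusion and committee machinery without any trees.

What the generator does *not* emulate: heavy-tailed expression noise,
probe-level artefacts, batch effects, and gene–gene correlation structure
beyond the optional blocks. Passing tests on this generator therefore
demonstrate that the pipeline's machinery is correct and that it recovers
planted signal; they do not certify performance on real microarray data,
where feature correlations and distribution shift between cohorts dominate.

The study conditions used by the test suite and the acceptance script:
the separable binary fixture is 30 + 30 samples × 1000 genes with 10
informative genes at shift 5; the pool-size check uses 40 × 1000 with 15
informative at shift 2; the multiclass experiment is 3 × 15 samples × 400
genes with 12 informative at shift 4. The end-to-end runs use a scaled-down
search (100 candidates, population 30, 30 generations, 10 repeats) — the
phase dynamics are already clearly expressed at these sizes.

## Design decisions that were genuinely open

* **Fold→phase mapping.** The two-split scheme requires only that the two
  validation folds differ; `val1 = C`, `val2 = B` was adopted and exposed as
  an argument of `assign_phase_folds()`.
* **Fitness granularity.** Accuracy on `val1` (holdout) is the default;
  the stratified 10-fold alternative is provided as `fitness_cv = "10fold"`
  (see above).
* **Phase-4 "re-scoring".** Refitting the terminal trees on `train2` before
  re-scoring (`phase4 = "refit"`, the default) gives the second split a real
  say in which individuals survive — otherwise the individuals are merely
  re-measured, and trees that overfit split 1 keep their structure. The
  cheaper `phase4 = "rescore"` mode is provided for comparison.
* **Selection scheme.** Binary tournament with elitism 1: robust for small
  populations, minimal selection pressure to tune, and elitism makes the
  best-fitness trace non-decreasing, which the tests assert.
* **Mutation granularity.** The 0.4 rate is interpreted per individual (one
  uniformly chosen node changes), not per node — per-node mutation at 0.4
  would randomise most of a 13-node individual every generation.
* **Per-tree subsampling.** Every candidate tree draws its own balanced
  subsample (bagging-style), rather than all trees sharing one subsample —
  sharing would collapse the sample-level diversity the subsample exists to
  provide.
* **Above-average strictness.** Strict `>` with an all-equal fallback, both
  for candidate trees and for individuals.

## Known limitations

* Base learners are limited to CART trees; the `base_classifier` record
  structure (model + feature subset + cached votes) is the seam where SVMs
  or kNN could be plugged in, but no such alternative is implemented.
* The forward search is greedy over pairs; it does not revisit earlier
  additions, and with many identical candidates it will absorb them all.
* OVR with very small classes is structurally data-starved (see above).
* The Relief implementation is a single-pass kernelised variant (hit/miss
  contributions weighted by `exp(−d/σ)` over all neighbours); it is not the
  iterated reweighting scheme some libraries ship.
* Evolution, candidate training and the forward search are deterministic
  given `seed`, but not reproducible across R versions if the underlying
  RNG algorithms change.
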