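---
title: "Classifying streptavidin-binding peptides with a downsampling SVM ensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying streptavidin-binding peptides with a downsampling SVM ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Phage-display biopanning selects peptides for affinity to a target, but the
output is contaminated by target-unrelated peptides (TUPs). A prominent class
of TUPs binds streptavidin (SA), the anchoring reagent routinely used to
capture biotinylated targets: whenever streptavidin is present in the panning
system, streptavidin-binding peptides (SBPs) creep into the hit list. The
same peptides are *desired* binders when streptavidin itself is the target,
for instance when developing affinity tags. Either way, one wants a fast
in-silico answer to the question: *is this peptide likely to bind
streptavidin?*

`sbpred` answers it with a supervised classifier trained on labelled
biopanning peptides: positives from experiments where streptavidin was the
intended target, negatives from experiments with no streptavidin in the
system.

## Model and procedure

### Composition features

A peptide of length $L$ over the 20-letter amino-acid alphabet is encoded by
its **amino acid composition** (AAC) or **dipeptide composition** (DPC):

$$\mathrm{AAC}_i = \frac{x_i}{\sum_{i=1}^{20} x_i}, \qquad
  \mathrm{DPC}_j = \frac{y_j}{\sum_{j=1}^{400} y_j},$$

where $x_i$ counts residues of type $i$ and $y_j$ counts occurrences of
dipeptide $j$ among the $L-1$ overlapping adjacent pairs. Both vectors are
stochastic (sum to 1). Two conventions are worth making explicit because the
composition definition alone does not force them:

* **Dipeptide windowing is overlapping and linear.** The $L-1$ adjacent
  pairs of the linear sequence are counted; no wrap-around pair is added for
  circular peptides, because circular peptides are linearized (clamp
  cysteines stripped) during preprocessing, before any encoding.
* **Normalization precedes selection.** Optimized subsets (below) are column
  selections of the full 20- or 400-component composition, so selected
  vectors are sub-stochastic. The alternative — renormalizing over the
  selected columns — would make a feature's value depend on which other
  features survived selection, which is both harder to interpret and
  unstable under reselection.

Columns are always ordered alphabetically (`A`…`Y`; `AA`…`YY`) so feature
matrices and model files are reproducible byte for byte.

### Accuracy-ranked forward selection

The optimized feature sets (OAAC, ODPC) come from a three-step wrapper
procedure: (i) each feature is scored alone by stratified 5-fold
cross-validated accuracy of an RBF-SVM on that single column; (ii) features
are added to an initially empty set in descending score order, re-evaluating
the growing set after each addition; (iii) the smallest prefix attaining the
maximum accuracy is kept. Ties in the ranking are broken lexicographically
by token and ties in prefix accuracy by preferring the smaller set; both
rules exist purely to make the trace deterministic.

The classifier used *inside* selection is configurable. By default it is a
single fixed cell $(c, g) = (8, 2^{-3})$ rather than a full grid search per
prefix: a grid re-run for each of 400 prefixes times 5 folds multiplies the
cost of selection by the grid size for a gain we found to be nil on
composition features, whose useful $(c, g)$ region is broad and flat.
Passing a multi-cell `svm_config` as `selection_config` restores the
grid-per-prefix behaviour.

Selection is by default performed once on the full training pair, and the
subsequent cross-validation reuses the selected set. This mirrors the
evaluation protocol that published accuracies of this family of predictors
are computed under, but it lets information from the held-out folds leak
into the feature choice. `cross_validate(..., nested = TRUE)` re-selects
inside every training fold and is the statistically honest variant; expect
its accuracy estimate to be a little lower.

### Downsampling ensemble

Training data are strongly imbalanced (hundreds of positives versus
thousands of negatives). Instead of reweighting, the package trains a
**voting ensemble**: `n_subsets` (default 10) negative subsets of the
positive-set size are drawn uniformly without replacement *within* a subset
and independently *across* subsets (a negative may recur in several
subsets; the draws are not a partition — the ten draws are repetitions of
one downsampling experiment, not a disjoint cover). Each balanced pair
trains one RBF-SVM submodel: grid search over $(c, g)$ by stratified 5-fold
CV accuracy (ties to smallest $c$, then smallest $g$), a final fit on the
whole pair, and a Platt sigmoid fitted to 5-fold cross-validated decision
values so each submodel emits a calibrated probability. Because composition
features already live in $[0,1]$, no additional feature scaling is applied
anywhere — which also keeps the kernel width $g$ interpretable across
implementations.

A prediction for a query peptide is:

* `mean_probability` — the arithmetic mean of the submodel probabilities;
* `votes` — how many submodels individually give probability ≥ 0.5 (a
  reliability indicator, deliberately independent of the user threshold);
* `call` — "SBP" iff the mean reaches the threshold `tp` (default 0.5).
  Users screening out suspected TUPs should lower `tp`; users shortlisting
  novel binders with high confidence should raise it (e.g. 0.95).

The calibration is fitted by this package (a Newton iteration on the
regularized sigmoid likelihood, the standard formulation) on seeded
cross-validated decision values rather than delegated to the SVM library's
internal calibration, because the library's internal shuffle is not
controllable from R and the package guarantees bit-for-bit reproducible
training under a fixed seed.

### Evaluation

Performance is reported as sensitivity, specificity, accuracy and Matthews
correlation from the pooled held-out confusion table,

$$\mathrm{Sn} = \frac{TP}{TP+FN},\quad \mathrm{Sp} = \frac{TN}{FP+TN},\quad
  \mathrm{Acc} = \frac{TP+TN}{TP+FP+TN+FN},$$
$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
  {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},$$

with MCC defined as 0 when a denominator factor vanishes. The ROC curve
sweeps the decision-value threshold over all distinct scores with tied
scores grouped into a single step; the trapezoidal AUC then equals the
Mann–Whitney pair statistic exactly, which the test suite verifies by brute
force. Cross-validation folds are stratified — with ~400-sample pairs,
unstratified folds make Sn/Sp estimates needlessly noisy.

Ensemble-level accuracy is the mean of the ten per-pair cross-validation
accuracies (reported with their standard deviation), with a pooled ROC over
all held-out decision values; per-pair reports are retained alongside.

Two significance tools accompany the point estimates:

* **Label-permutation test** — the pair's labels are shuffled and the whole
  cross-validation repeated per permutation; the p-value is the fraction of
  permuted accuracies *strictly* greater than the observed one, and a count
  of zero is reported as the upper bound $p < 1/N$ rather than 0.
* **Chi-square comparison of positive rates** — Pearson chi-square on the
  2×2 table of SBP/non-SBP calls in two batches, one degree of freedom,
  two-sided, without Yates continuity correction (expected counts in the
  intended use are in the hundreds, where the correction is immaterial;
  fixing the convention keeps results bit-reproducible).

## The synthetic benchmark

Real training collections come from a biopanning database and ship as
supplementary material of the primary literature; they are not
redistributed here. For development and testing the package generates a
benchmark that reproduces the *structure* of those data:

* lengths from a rounded normal with mean 9 and sd 3.5, truncated at 3 —
  matching the published summary statistics of the training collection
  (true per-library length mixes, e.g. 7-mer vs 12-mer libraries, are not
  public);
* positives: 90% carry the canonical streptavidin-binding motif His-Pro-Gln
  (HPQ) at a uniform random position; background residues follow a
  first-order chain in which the dipeptides repeatedly reported as
  discriminative for streptavidin binding (HP, PQ, PP, LP, PL, PS, SP, TP)
  have their transition probability multiplied by 3 — so the class signal
  is carried by exactly the tokens a correct selector should find;
* negatives: i.i.d. uniform residues, with any draw containing the motif
  rejected, giving a controllable Bayes error;
* default sizes 199 positives / 1990 negatives, reproducing the 1:10
  training geometry of ten balanced downsampled pairs;
* sets are duplicate-free and mutually overlap-free by construction, so
  they pass preprocessing with zero removals.

The defaults (motif rate 0.9, enrichment weight 3) were fixed once as a
realistic signal level — strong motif enrichment with a minority of
motif-free binders — and are not tuned. What passing on this benchmark
shows: the full pipeline (encoding → selection → ensemble → evaluation)
recovers a planted dipeptide signal and ranks feature kinds in the expected
order (ODPC above AAC). What it does not show: performance on real
biopanning data, whose negatives are far from residue-uniform, whose motif
dictionary is richer than HPQ, and whose positives share library-design
biases with the negatives.

## Numerical and design choices

* **Grids.** The canonical coarse libsvm grid
  ($c \in 2^{\{-5,-3,\dots,15\}}$, $g \in 2^{\{-15,-13,\dots,3\}}$) is the
  default for single fits; the heavier protocols (per-pair selection and
  ensemble cross-validation) default to the 4×4 subgrid
  $c \in 2^{\{-1,1,3,5\}}$, $g \in 2^{\{-7,-5,-3,-1\}}$ centered on where
  composition features place the optimum.
* **Problem sizes in the shipped checks.** The test suite and the
  reproduction script run the full default benchmark (199/1990, ten pairs)
  for the ensemble comparison, 100 permutations for the significance check
  on one pair, and 50 repetitions of a 39-permutation test on no-signal
  data for the p-value calibration check; smaller seeded sets exercise the
  individual operations.
* **Degenerate inputs.** Preprocessing an entirely filtered-out set, single
  class labels, a subset size exceeding the negative pool, unknown
  descriptor tokens, truncated or version-mismatched model files all raise
  explicit errors. Peptides a model cannot encode (too short, residues
  outside the alphabet) yield per-record NA predictions with a note rather
  than failing a batch.
* **Cysteine stripping** removes at most one cysteine per end and only from
  records flagged circular ("at both ends" is read as "at either end": a
  circular display construct with a clamp cysteine on only one side loses
  only that one). Topology is input metadata (a `circular` token on the
  FASTA description line, or a constructor/CLI flag); nothing is inferred
  from C…C patterns, which would misclassify linear cysteine-rich peptides.
* **Ambiguity letters.** Besides X/B/Z, the letters J/O/U are excluded:
  the predictor is defined over the 20 standard residues.
* **Consensus features.** Selection runs per pair, so ten (possibly
  different) optimized sets exist; the ensemble reports the tokens selected
  in at least half of the pairs as its consensus set. This is a reporting
  convention — each submodel predicts with its own set.

## Known limitations

* The default evaluation protocol shares feature selection across CV folds
  (see above); use `nested = TRUE` for unbiased estimates.
* Calibrated probabilities are only as good as the balanced training pairs;
  on wildly imbalanced application sets the mean probability ranks well but
  its absolute scale should not be over-interpreted.
* The generator does not simulate phage propagation bias or library codon
  schemes; a benchmark accuracy is not a field accuracy.
* Training is quadratic-ish in pair size; the package targets
  peptide-library scale (hundreds per class), not proteome scale.
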