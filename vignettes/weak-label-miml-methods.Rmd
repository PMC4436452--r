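---
title: "Weak-label multi-instance multi-label learning for protein function"
author: "mimlwel authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weak-label multi-instance multi-label learning for protein function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimlwel)
```

## The problem

Most genomic proteins are multi-domain: each conserved domain can carry a
molecular function of its own, and the protein's annotated function set is
the union of what its domains do. Two features of real annotation data shape
the learning problem:

* **Multi-instance, multi-label (MIML) structure.** A protein is a *bag* of
  domain *instances*, associated with a *set* of Gene Ontology (GO)
  molecular-function terms. Which domain carries which function is not
  recorded.
* **Weak labels.** Curated annotation is incomplete: an annotated term is a
  true positive, but an *absent* term means "unknown", not "absent". The
  per-label fraction of true positives that are actually observed is the
  *weak-label ratio* (W.L.R.), `||Yhat[,l]||_1 / ||Y[,l]||_1`.

This package implements the full analysis pipeline: featurization of domain
sequences, GO label-matrix construction, controlled label masking, the
MIMLwel learner, a MIML-kNN baseline, and a repeated cross-validation
protocol — plus a synthetic-data generator so that every stage is testable
without access to proteome databases.

## Featurization: conjoint triads

Each domain sequence is encoded as a frequency vector over 3-residue
windows after mapping the 20 standard amino acids to 6 classes, giving
`6^3 = 216` triad types. The exact 6-class partition behind published
216-dimensional encodings is not standardized, so the package default is a
Dayhoff-style grouping — {C}, {A,G,P,S,T}, {D,E,N,Q}, {H,K,R}, {I,L,M,V},
{F,W,Y} — and the partition is configurable (`triad_alphabet()`,
`read_alphabet_config()`). Ambiguity codes (B, J, O, U, X, Z) map to no
class; a window containing one is skipped rather than the sequence
rejected, and counts are normalized by the number of *valid* windows so
every encoding lies on the probability simplex.

```{r}
round(which(encode_triads("ACDEF") > 0))  # three windows, three triad types
```

## Labels: GO molecular function with the true-path rule

Annotations are propagated up the `is_a` hierarchy of the
molecular-function ontology (`parse_obo_subset()`,
`propagate_annotations()`): a term implies all of its ancestors. Only
`is_a` edges are used — `part_of` and other relations are ignored as the
conservative closure. The ontology root (`GO:0003674`) is positive for
every annotated protein, carries no information, and is never emitted as a
label. Label columns are ordered lexicographically by GO id and rows follow
bag input order, so matrices are deterministic.

## The MIMLwel learner

**Bag embedding.** A bag `X` is mapped to a fixed-length vector by RBF
responses to `K` *medoid bags*:
`phi_k(X) = exp(-d(X, M_k)^2 / (2 (mu * delta)^2))`, plus a constant bias
coordinate. The medoids are chosen by PAM-style k-medoids under the average
Hausdorff distance

`d_avg(A, B) = (sum_a min_b ||a-b|| + sum_b min_a ||a-b||) / (|A| + |B|)`,

`K = max(1, round(alpha * m))` is a fraction `alpha` of the training bags,
and the base width `delta` is the mean nearest-medoid distance, scaled by
`mu`. The two embedding parameters `alpha` (capacity) and `mu` (kernel
width) are the ones worth sweeping; `param_grid()` reproduces the
`mu in 0.2..1.0` by `alpha in 0.02..0.1` grid, and `mu = 1.0, alpha = 0.1`
is the default operating point.

**Objective.** With the embedded training matrix `Phi` (m x d), observed
labels `Yhat`, and a corrected matrix `Ybar` to be learned, the model
minimizes over `W = [w_1 ... w_L]` and `Ybar`

```
eta * sum_l sum_i (w_l' phi_i - (2 ybar_il - 1))^2
  + sum_{pairs l<l', R_ll'=1} ( sum_r sqrt(W[r,l]^2 + W[r,l']^2) )^2
```

subject to `ybar_il = 1` wherever `yhat_il = 1` and, per label,
`||Ybar_l - Yhat_l||_1 <= floor(epsilon * ||Yhat_l||_1)`. The loss `V` is
squared error on targets coded ±1 — chosen because it admits a closed-form
least-squares oracle in the uncoupled limit, which the test suite uses to
verify the solver. The second term is a squared group-(2,1) penalty over
*related label pairs*: rows of the stacked pair `[w_l w_l']` are driven to
zero jointly, encoding the assumption that highly relevant labels share
common instances. Relatedness `R` is estimated from the observed label
columns: `R_ll' = 1` iff their cosine similarity reaches `tau` (default
0.5).

**Optimization.** Alternating minimization. The W-step minimizes the smooth
objective (row norms smoothed by `sigma = 1e-8`) by gradient descent with
Barzilai-Borwein step proposals and Armijo backtracking, run until the
relative objective change stays below `tol = 1e-6` (for three consecutive
iterations, so a single plateau step is not mistaken for convergence) or
500 iterations. The Ybar-step is exact: per label, among entries with
`yhat = 0`, the top-`floor(epsilon * ||Yhat_l||_1)` scores are flipped to 1
— but only where the score is strictly positive, which prevents arbitrary
tie-breaking among hopeless candidates and guarantees each flip decreases
the objective. Both steps descend, so the recorded objective trace is
non-increasing; the outer loop stops when `Ybar` is stable (at most
`max_outer = 20` rounds).

**Defaults.** `eta = 1` (risk weight), `epsilon = 0.2` (correction budget),
`tau = 0.5` (relation threshold). These are pragmatic defaults, exposed as
arguments; no published values exist for them in this setting.
Predictions threshold the score at 0, the symmetric boundary under ±1
coding.

## The MIML-kNN baseline

For a query bag, the voters are its `n_neighbors = 10` nearest training
bags plus the *citers* — training bags that would count the query among
their own `n_citers = 20` nearest bags. A label's score is the fraction of
voters positive for it; the call threshold is 0.5. Distance ties resolve
toward the lower training index. This is a deliberate simplification of the
original two-stage MIML-kNN (which post-processes neighbor counts with a
learned linear transform); only the two published hyperparameters are kept,
and the comparison on synthetic data is qualitative. Whether the original
used average or maximal Hausdorff distance internally is not stated; both
are implemented (`distance = "avg"` is the default).

## Evaluation protocol

`run_repeated_cv()` repeats k-fold cross-validation (default 10 folds, 10
repetitions; tests and examples use smaller sizes). Per fold, *training*
labels are masked to the target W.L.R. by per-column subsampling —
`max(min_keep, round(r * p))` positives retained, round half to even,
`min_keep = 1` so no label vanishes — and held-out bags are scored against
their *full* labels: recovering masked positives is precisely what a
weak-label learner is for. Fully unlabeled proteins are realized by the
held-out fold itself, not by a separate masking mode. Fold assignment seeds
depend only on `(seed, repetition)`, never on the ratio or the method, so
`wlr_sweep()` and `compare_methods()` are paired fold-for-fold. Folds are
plain random, not label-stratified: with hundreds of mostly-rare labels and
a few hundred bags, stratification is infeasible.

Metrics: Hamming loss, macro-F1 and micro-F1, with F1 defined as 0 whenever
its denominator vanishes — with several hundred labels and ~3 positives per
protein most labels are unpredicted, and any other zero-division convention
inflates macro-F1. Method comparisons use two-sided paired t-tests on the
rep x fold cells at the 95% level; a comparison is marked when the focal
method is both better on the metric and significantly different
(`compare_methods()`). Zero-variance differences get the convention `p = 1`
for a zero mean difference and `p = 0` otherwise.

Whether published protocols mask once globally or per training fold is
typically unstated; masking per training fold is chosen here because test
labels must stay full for scoring.

## The synthetic-data generator

`generate_dataset()` emulates the statistical profile of curated bacterial
proteome MIML datasets: a few hundred bags, `3.2 ± 1.2` instances per bag
(rounded truncated normal), a mean of `3.3` labels per bag, and
216-dimensional instances on the probability simplex, like triad
frequencies. Mechanism:

* Each label has a sparse simplex *prototype* (normalized Gamma(0.05)
  draws); a bag positive for a label contains at least one noisy copy of
  that label's prototype (Gaussian noise, sd `prototype_noise = 0.015`,
  then Euclidean projection back onto the simplex). Same-family domains
  have nearly identical triad profiles, hence the small default.
* Label popularity is Zipf-like with exponent 1.0 over popularity ranks,
  with the head flattened across the top ~30% of labels
  (`w_l ~ 1/max(l, ceil(0.3 L))`). The long tail reproduces the rarity that
  makes macro-F1 tiny on real data; the flattened head keeps every label's
  frequency realistic — no GO molecular-function term annotates a majority
  of proteins, which a pure Zipf head would imply at small `L`.
* Three *correlated pairs* of labels share a prototype, and a sampled pair
  member recruits its partner with probability 0.5 — highly relevant labels
  share common instances, the assumption the group penalty exploits. The
  default pairs sit just past the flattened head: frequent enough to
  co-occur, without further inflating the top labels.
* The per-bag label count is `min(n_i, 1 + Poisson(lambda), L)`; `lambda`
  is calibrated by root-finding so that the realized labels-per-bag mean
  hits the target despite the cap (the cap keeps one instance available
  per independently drawn label). Slots not needed to realize a label are
  filled with background simplex noise (probability `background_rate =
  0.5`) or another noisy prototype copy. The labels-per-example *standard
  deviation* is not independently controlled; it emerges from the
  popularity law and is smaller than in real data, where a few hub proteins
  carry very many terms.

What passing tests on this generator do and do not show: they demonstrate
that the pipeline recovers planted signal, respects its constraints, and
reproduces the qualitative W.L.R. trend (performance rises as more labels
are observed). They do not certify performance on real proteomes, whose
instances are not exactly prototype-plus-noise and whose label sets are far
larger and sparser.

## Numerical choices and degenerate inputs

* Masking uses round-half-to-even and a `min_keep = 1` floor; an all-zero
  label column would be unlearnable and make macro-F1 ill-defined.
* If the mean nearest-medoid distance is 0 (degenerate data), the kernel
  width falls back to the smallest positive medoid-medoid distance, else 1.
* k-medoids breaks all ties toward the lowest index and is deterministic
  given its seed; swaps must improve the cost by more than 1e-12.
* The group penalty's row norm is smoothed with `sigma = 1e-8`, far below
  test tolerances, to be differentiable at zero rows.
* Distance matrices are symmetrized (`(D + t(D)) / 2`) to absorb
  floating-point asymmetry before clustering.
* Dataset and model files are JSON with explicit schema versions; numbers
  are written at full precision so round-trips are exact and repeated runs
  are byte-identical (timestamps live only in run manifests).

## Problem sizes

The shipped tests and the reproduction script run on scaled-down problems
chosen to exercise every code path at interactive speed: metric oracles on
8 x 6 matrices, solver oracles on 20-30 bags, cross-validation sweeps on
m = 120 bags with 30 labels (3 folds, 2 repetitions), and signal-recovery
checks on m = 200 bags with 20 labels. The package defaults
(`synthetic_spec()`, 10 x 10-fold CV) correspond to the full-size protocol.

## Known limitations

* The exact functional forms of the original learner's loss and bag-level
  feature map are not published in a recoverable form; the squared loss and
  the Hausdorff k-medoids RBF embedding used here are explicit,
  documented reconstructions that keep the published parameter names,
  ranges and roles, and both are isolated behind `fit_mimlwel()` /
  `fit_bag_embedding()` so alternatives are drop-in.
* The 6-class triad partition is a declared substitute for an unpublished
  grouping and is configurable.
* Redundancy removal (sequence clustering) and conserved-domain detection
  are external preprocessing; the package consumes their tabular outputs.
* MIML-kNN is simplified to direct neighbor/citer voting.
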