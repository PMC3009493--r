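---
title: "Methods: simultaneous feature and sample selection for miRNA tumor classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simultaneous feature and sample selection for miRNA tumor classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfssclass)
```

## The problem

miRNA expression panels used for tumor-of-origin prediction carry a few
hundred features for a few dozen training tissues per study. Only a small
subset of miRNAs is informative for any given set of tumor classes, and not
every training sample is equally trustworthy: tissue-specific regulation
means a marker pattern holds within a subset of samples, not across the
whole panel. The method implemented here therefore selects *features and
samples simultaneously*: a biclustering stage proposes (miRNA set, sample
set) blocks that are co-expressed, an external knowledge source — a
bipartite network of literature-verified cancer–miRNA dysregulation
associations — filters those blocks to the ones with experimental support,
and a centroid-based classifier is trained on the reduced matrix.

## Preprocessing

Raw bead-array style intensities are floored at 1 and log2 transformed
(`log2_transform()`). Two minimum-expression filters are exposed through
`filter_min_expression()`: a *minimal-cutoff* mode (keep a miRNA iff it
reaches 7.25 on the log2 scale in at least one sample) and a *prevalence*
mode (keep a miRNA iff it reaches 8 in at least 10% of samples;
"at least 10%" rounds up, so 43 samples require 5). The threshold
comparison is inclusive (`>=`). Features are then centered and scaled to
mean 0 and standard deviation 1 per miRNA; we use the sample
(n − 1 denominator) standard deviation, the usual convention in expression
analysis. Standardization is always *fitted on training data only* and its
(center, scale) applied to held-out or test samples
(`apply_standardization()`); fitting it on pooled train + test data would
leak test information into every later stage. Zero-variance features are an
error, not a silent drop — on real panels they indicate a filtering problem
upstream.

## The biclustering stage

The search operates on a trinary version of the standardized matrix:
entry (i, j) is +1 if the standardized expression is at least `t`, −1 if at
most −t, else 0, with `t = 1` (one standard deviation) by default. Nonzero
entries are "responses" and define a bipartite miRNA–sample graph. Under a
uniform background null in which every pair responds independently with the
observed density `p_hat`, and an alternative in which pairs inside a
bicluster respond with probability `p_c` (default 0.9), the
log-likelihood-ratio weight of a responding pair is `log(p_c / p_hat)` and
of a non-responding pair `log((1 − p_c) / (1 − p_hat))`. A bicluster's score
is the sum of its block's weights, so maximizing score finds statistically
surprising dense blocks.

The search itself is deliberately simple and fully testable:

1. **Seeding.** For every sample vertex of degree at most `d` (30), all
   subsets of its responding miRNAs of size 2..`k` (3) are enumerated; a
   subset's candidate block pairs it with every sample responding on all of
   its members. The `n_keep` (20) best candidates per vertex are kept.
2. **Local improvement.** Each candidate is hill-climbed by the single
   feature/sample addition or removal with the largest score gain until no
   move improves the score. The score strictly increases per move and is
   bounded by the sum of positive weights, so the loop terminates. Blocks
   never shrink below 2 × 2.
3. **Non-redundant emission.** Improved blocks are emitted in score order,
   skipping blocks whose Jaccard overlap (on the union of feature and
   sample sets) with an already-emitted block exceeds `max_overlap` (0.25).

Design choices made here, with their reasons:

* **Uniform-density null.** A degree-corrected null would model hub
  features more faithfully but is not identifiable from the small matrices
  this pipeline targets and makes the score non-decomposable; the uniform
  null keeps the heavy-subgraph semantics and admits an exhaustive-
  enumeration oracle, which the test suite uses on 8 × 6 instances.
* **Sign handling.** Up- and down-responses both count as responses; the
  sign is retained in the graph but coherence is not enforced, since
  co-regulated blocks may contain both directions relative to the panel
  mean. Tests that need a coherent planted block simply plant one.
* **Determinism.** Vertices are ordered lexicographically at graph
  construction and every tie (move choice, candidate ranking, emission) is
  broken by that order, so the output is a pure function of the input.

Degenerate inputs: a matrix with no responses returns an empty list with a
warning; `p_c` must strictly exceed the observed density, otherwise the
model is uninformative and construction fails.

### What the planted-block benchmark shows

The recovery benchmark plants one 6 × 5 block, shifted by 3 noise standard
deviations, in a 15 miRNA × 40 sample matrix, then runs standardization,
discretization and the search at defaults. The geometry matters: the block
must occupy a minority of samples (here 12.5%), because per-feature
standardization absorbs a block that spans about half the samples into the
feature's own location and scale, pushing its standardized values down to
the discretization threshold. At `t = 1` the background response density is
2(1 − Φ(1)) ≈ 0.32, so in matrices with many more samples than this,
sample-selection effects let spurious blocks compete with a 6 × 5 signal;
at this size the planted block wins cleanly. On the fixed benchmark seed
the top block recovers the plant exactly (Jaccard 1.0); across other seeds
a boundary feature or sample can legitimately swap in or out — those
variants score at least as high under the objective — so recovery is
asserted on the fixed instance, not in distribution. Sparse, clean response
structure (an all-up block over 5% trinary noise) is recovered exactly at
20 × 12 as well.

## Network-based selection

The cancer–miRNA network is a bipartite graph G = (U, V, E): U cancer
types, V miRNAs, and an edge whenever a miRNA is reported dysregulated in a
cancer type (the published instance of such a network has |U| = 31 and
|V| = 192; the package reads any edge table of that shape). Identifiers are
matched case-insensitively after trimming because literature-derived names
vary in case; duplicate edges collapse, and contradictory per-edge
directions collapse to "mixed". Edge direction is ignored by the selection
rules — association is what the method uses.

A bicluster is **potential** if at least one (class(sample), miRNA) pair of
the bicluster is a network edge. From a potential bicluster *all* miRNAs
are kept (members of one bicluster are likely co-regulated, so the
unsupported members still carry signal) but only the **relevant** samples —
those whose class is adjacent to at least one miRNA *of that bicluster*.
We read the relevance rule per-bicluster rather than "the class appears
anywhere in the network": the per-bicluster reading makes relevance a
property of the evidence at hand and is what makes it possible for a class
to lose all its samples and drop out of the training set (the looser
reading is available via `any_mirna = TRUE`). Dropped classes are always
listed in the selection report, mirroring how a tumor panel can lose, e.g.,
classes whose markers never co-cluster with their tissues. The reduced
training set is the union over potential biclusters of their features and
relevant samples; it is invariant to bicluster order and can only grow when
network edges are added.

## The classifier

For miRNA *i* and class *k* with class centroid x̄_ik, overall centroid
x̄_i, pooled within-class standard deviation s_i and fudge constant
s_0 = median_i(s_i):

d_ik = (x̄_ik − x̄_i) / (m_k (s_i + s_0)), with m_k = sqrt(1/n_k − 1/n).

This m_k makes m_k·s_i the standard error of the numerator under a common
within-class variance (the class mean is part of the overall mean, hence
the minus sign); the more conservative sqrt(1/n_k + 1/n) variant used by
some shrunken-centroid implementations is available via
`mk_form = "sum"`. Soft thresholding at Δ gives
d′_ik = sign(d_ik)·max(|d_ik| − Δ, 0); features with all-zero d′ rows are
dropped — the selected set is nested and non-increasing in Δ. Shrunken
centroids are x̄′_ik = x̄_i + m_k(s_i + s_0)d′_ik.

The *uncorrelated* variant prunes redundant survivors: features are ranked
by max_k |d_ik| (descending, ties by id) and kept greedily iff their
absolute Pearson correlation with every kept feature is at most ρ, so of a
correlated pair the one with the smaller relative difference is the one
removed. Three choices were genuinely open and are fixed as follows:
ranking uses the *pre-shrinkage* |d| (shrunken values tie at zero for
many features; `use_shrunken = TRUE` switches), correlation is compared as
an absolute value (anti-correlated features are as redundant as correlated
ones for a quadratic discriminant), and the scan is greedy from the
strongest feature down (any order-free formulation is an NP-hard maximum
independent set). At ρ = 1 nothing is pruned and USC coincides with SC;
the package also exposes `method = "sc"` which skips the correlation scan
entirely, and the test suite checks the two paths predict identically at
ρ = 1 on seeded data.

Classification minimizes
δ_k(x*) = Σ_i (x*_i − x̄′_ik)²/(s_i + s_0)² − 2 log π_k over classes, with
empirical priors π_k = n_k/n by default (`prior = "uniform"` for 1/K).
Exact ties go to the lexicographically first class label and are flagged in
the output rather than silently resolved.

## Parameter tuning

(Δ, ρ) are tuned by repeated stratified fourfold cross-validation
(10 repeats by default). Each class's samples are dealt cyclically to folds
after a seeded shuffle, so per-class fold sizes differ by at most one;
single-sample classes cannot be held out and are pinned to training with a
warning. Standardization and all centroid statistics are recomputed inside
each training split — the held-out fold never influences the fit. Grid
cells whose fit fails in a split (e.g. Δ beyond every |d_ik|) count as
error 1.0 there and are flagged when they fail everywhere. The default
grids are Δ ∈ {0, 0.1, …, 2.0} and ρ ∈ {0.5, 0.6, …, 1.0} — Δ on the scale
of standardized relative differences where the usable range ends when the
feature set empties, ρ in the range where pruning is meaningful without
discarding moderately correlated markers. The optimum is the minimum mean
error, with ties broken toward larger Δ and then smaller ρ: among equally
accurate cells, prefer the model with fewer, less redundant features.

The pipeline runs biclustering and network selection once on the full
training set and cross-validates only the classifier on the reduced matrix,
matching the method's published flow. Because the held-out folds then took
part in the selection stage, `sfss_cross_validate()` (or `cv: strict: true`
in the pipeline configuration) re-runs the entire selection stack inside
every training split for leakage-free benchmarking; it is several times
slower and is not the default.

## Synthetic data: what it does and does not emulate

`simulate_classification_data()` draws i.i.d. N(0, 1) background expression
and shifts each class's `p_info` informative miRNAs by `effect` in that
class only — the additive marker model on the standardized log scale the
pipeline assumes. `simulate_planted_biclusters()` plants shifted blocks in
Gaussian noise, and `simulate_network()` turns the planted truth into a
cancer–miRNA network with tunable `coverage` (probability a true
association is present) and `false_edge_rate`. The default study
conditions — 5 classes × 20 training samples, 100 miRNAs with 5 informative
per class at 3 sd, full coverage, no false edges — give a problem where the
pipeline should succeed nearly perfectly, and the acceptance checks assert
exactly that (≥ 80% marker recovery, ≥ 90% held-out accuracy, CV optimum
within 0.02 of the grid-best held-out error).

These generators do *not* emulate heavy-tailed intensity noise,
array/batch effects, correlated marker blocks within a class, label noise,
or the biases of literature mining (which over-reports well-studied miRNAs).
Passing tests therefore demonstrate correctness of the algorithms and
sane behavior under the stated noise model — not expected accuracy on any
real tumor panel.

## Numerical choices and limitations

* Tolerances: standardization asserts mean/sd to 1e−9; local improvement
  requires a gain above 1e−9 to move (guards float cycling); prediction
  ties use a 1e−12 relative tolerance; hand-computed fixtures are checked
  to 1e−9.
* Problem sizes in the test suite: the end-to-end benchmark is
  100 miRNAs × 100 training / 25 test samples; bicluster oracles run at
  8 × 6 (exhaustive) and 15 × 40 (planted); equivalence checks use
  20 seeded 30 × 18 data sets. These sizes exercise every code path while
  keeping the default suite fast.
* The biclustering stage seeds only from sample vertices with degree at
  most `d`; on very dense response matrices (many samples responding on
  most features) no vertex qualifies and the search returns nothing —
  raise `t` or `d` in that regime.
* `read_gct()` is fixed to the GCT v1.2 dialect; missing cells are
  rejected unless row-mean imputation is requested explicitly. CLS files
  carry no sample identifiers, so labels are joined positionally with the
  expression columns (or explicitly via the `sample_ids` argument) —
  class labels always come from a label file, never from parsing sample
  names.
* The command-line surface is a thin `run` wrapper
  (`inst/cli/sfssclass.R`) over `run_sfss()`; individual stages are plain
  exported functions, which is the natural interface for the R users this
  package targets, so no per-stage subcommands are provided.
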