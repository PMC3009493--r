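# sfssclass

Multiclass tumor-of-origin classification from miRNA expression profiles,
with **simultaneous feature and sample selection** (SFSS).

Tumor panels profiled for a few hundred miRNAs routinely carry more features
than informative markers, and not every training tissue is equally useful
either. This package implements the SFSSClass approach: a biclustering stage
finds groups of miRNAs that are co-expressed within subsets of samples, a
literature-derived bipartite *cancer–miRNA* association network keeps only
the biclusters (and, within them, the samples) with experimental support,
and the reduced training set is classified with the **uncorrelated shrunken
centroid (USC)** classifier, tuned by ten random fourfold cross-validations
over its shrinkage and correlation thresholds. It is aimed at researchers
classifying tumors or cell lines from bulk (or pseudobulk) miRNA expression
matrices in GCT format — including poorly differentiated tumors classified
against a more-differentiated training panel.

## The method

Let `x_ij` be the expression of miRNA *i* in sample *j* (*n* samples,
*K* classes, class *k* holding the `n_k` samples `C_k`).

**Shrunken centroids.** With the overall centroid `x̄_i`, class centroids
`x̄_ik`, pooled within-class standard deviation
`s_i² = (1/(n−K)) Σ_k Σ_{j∈C_k} (x_ij − x̄_ik)²` and fudge constant
`s_0 = median_i(s_i)`, the standardized **relative difference** is

    d_ik = (x̄_ik − x̄_i) / (m_k (s_i + s_0)),   m_k = √(1/n_k − 1/n)

Soft thresholding at the shrinkage level Δ gives
`d′_ik = sign(d_ik) max(|d_ik| − Δ, 0)`; miRNAs with a nonzero `d′_ik` for
at least one class are retained, and their shrunken class centroids are
`x̄′_ik = x̄_i + m_k (s_i + s_0) d′_ik`. USC additionally prunes redundant
markers: scanning the survivors by decreasing `max_k |d_ik|`, a miRNA is
dropped when its absolute Pearson correlation with an already-kept miRNA
exceeds the threshold ρ (at ρ = 1 USC is exactly SC). A new sample `x*` is
assigned to the class minimizing the discriminant score

    δ_k(x*) = Σ_i (x*_i − x̄′_ik)² / (s_i + s_0)² − 2 log π_k

**Simultaneous feature and sample selection.** Before classification, the
standardized training matrix is discretized to up/unchanged/down calls and
cast as a weighted bipartite miRNA–sample graph with likelihood-ratio
weights (`log(p_c/p̂)` for a responding pair, `log((1−p_c)/(1−p̂))`
otherwise); heavy subgraphs of this graph — biclusters — are found by seed
enumeration plus greedy local improvement. A bicluster is *potential* when
at least one of its (sample-class, miRNA) pairs is an edge of the
cancer–miRNA network; from each potential bicluster all miRNAs but only the
network-supported samples are kept, and the union over potential biclusters
is the reduced training set. Classes that lose all samples are dropped and
reported. (Δ, ρ) are then chosen by the minimum mean error over ten random
stratified fourfold cross-validations.

## Worked example

Everything below is synthetic and seeded, so it reproduces exactly:

```r
library(sfssclass)

sim <- simulate_classification_data(K = 5, p = 100, n_k = 20,
                                    p_info = 5, effect = 3, seed = 1)
net <- simulate_network(sim$truth, coverage = 1, false_edge_rate = 0, seed = 3)

std  <- standardize_features(sim$matrix)
bicl <- find_biclusters(build_graph(discretize(std)))
sel  <- build_training_set(bicl, std, net)
sel
#> sfss_selection: 21/45 potential biclusters -> 53 miRNAs x 84 samples, 5 classes kept

cv <- cross_validate(sel$matrix, repeats = 10, n_folds = 4, seed = 1001)
cv
#> usc_cv: 10 repeats x 4 folds, 21 x 6 grid; minimum mean error 0.0000 at (delta = 2, rho = 0.7)

fit <- usc_fit(sel$matrix, delta = 2, rho = 0.7)
fit
#> usc_model (USC): 22 features, 5 classes, delta = 2, rho = 0.7

te     <- simulate_classification_data(K = 5, p = 100, n_k = 5,
                                       p_info = 5, effect = 3, seed = 2)
pred   <- predict(fit, apply_standardization(te$matrix, std))
head(pred[, 1:3], 4)
#>   sample_id class   tie
#> 1      s001 colon FALSE
#> 2      s002 colon FALSE
#> 3      s003 colon FALSE
#> 4      s004 colon FALSE
mean(pred$class == te$labels[pred$sample_id])
#> [1] 1
```

Of 45 biclusters, 21 have network support; the reduced training set (53
miRNAs × 84 samples) keeps all five classes, cross-validation reaches zero
mean error, and the tuned model classifies all 25 held-out samples
correctly. The same flow runs from one configuration with `run_sfss()`
(see `?run_sfss`) or from a shell via `inst/cli/sfssclass.R`; real data
enter through `read_gct()`, `read_labels()` and `read_network()`.

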