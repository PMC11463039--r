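---
title: "Models and methods behind CrossKingdomNet"
author: "CrossKingdomNet maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind CrossKingdomNet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CrossKingdomNet)
```

# Scope

CrossKingdomNet analyses two-group, multi-kingdom (bacterial + fungal)
microbiome cohorts: it filters and merges relative-abundance profiles,
clusters samples by weighted similarity network fusion (WSNF), infers a
signed co-occurrence network per group with a compositionality-aware
four-method ensemble, compares the groups' attack robustness through
normalized natural connectivity, and detects keystone taxa by a
permutation test along the influence (IVI) axis. A synthetic-cohort
generator with planted ground truth backs every stage, so the whole
pipeline is testable end to end without any sequencing data.

This vignette records the models, the defaults and why they were chosen,
the numerical conventions, and the known limitations. Everything stated
here about behaviour is computed by the package's test suite or by
`scripts/acceptance.R`; no external results are quoted.

# Profiles: filtering and merging

Profiles are taxon-by-sample matrices (`AbundanceTable`, a
`SummarizedExperiment` subclass) in counts or relative mode. Taxon
filtering keeps taxa whose *mean* relative abundance (zeros included)
strictly exceeds a threshold — 1e-4 for bacteria, 1e-3 for fungi are the
conventional nasal-microbiome settings — and whose prevalence (fraction of
samples with a nonzero entry) strictly exceeds 10%. Both criteria use
strict inequalities, the conventional reading of "greater than"; the mean
(rather than per-sample maximum) is used because it is the standard
abundance summary for prevalence-abundance filters. Filtered tables are
open subcompositions (column sums at most 1); the cross-kingdom merge
concatenates the per-kingdom tables and re-closes every sample column to
sum 1.

A consequence worth knowing: merging *separately closed* kingdom profiles
forces each kingdom's total share to be equal in every sample. This is
unavoidable when the kingdoms are profiled by different instruments (MAG
catalogues vs. a fungal reference database), but it injects a per-sample,
per-kingdom scale that is not biological. Validation of the network
inference therefore uses single-kingdom synthetic cohorts, where the
planted ground truth survives closure intact; the merge convention is
exercised by the pipeline and clustering tests.

# The synthetic cohort generator

The generator is a latent Gaussian copula for compositions:

1. Per group, a sparse symmetric precision matrix $\Omega$ is planted on
   the latent log-abundance scale. Groups share a common edge backbone;
   a configurable fraction of edges is group-specific. Off-diagonal
   magnitudes are uniform on $[0.2, 0.4]$ and positive definiteness is
   enforced by diagonal dominance ($\omega_{ii} = 1 + \sum_j
   |\omega_{ij}|$), which yields latent partial correlations of roughly
   0.08–0.25 — a realistic effect-size regime for microbial association
   studies. The ground-truth *interaction sign* of an edge is
   $-\mathrm{sign}(\omega_{ij})$, i.e. the sign of the latent partial
   correlation.
2. Taxon means are log-normal with standard deviation `dominance`
   (log scale), shared between groups, with configurable log-fold shifts
   added to group 2 (`differentialTaxa`).
3. Latent log-abundances $z \sim N(\mu, \Omega^{-1})$ are exponentiated,
   closed to a composition, sampled to counts with a per-sample
   multinomial at `sequencingDepth`, and thinned by independent per-cell
   dropout (`zeroInflationProb`), which mimics sequencing dropout without
   disturbing the latent covariance.

Defaults emulate the cohort the package targets: 122 bacterial and 131
fungal taxa, two groups of 439 and 807 samples, and `dominance = 2.5`,
which at 253 taxa concentrates about three quarters of the total mean
relative abundance in the top-10 taxa. (At the scaled-down sizes used in
tests, smaller `dominance` values of 0.5–1.5 are used, since dominance
interacts with taxon count.) A latent log-normal/multinomial model was
chosen over dynamical (Lotka–Volterra) simulation because it encodes
exactly the conditional-dependence structure the inference stage is
supposed to recover, giving a clean planted-edge recovery criterion.

What the generator does *not* emulate: phylogenetic correlation between
taxa, batch or covariate structure, over-dispersion beyond the
multinomial, and structured (abundance-dependent) dropout. Passing the
recovery tests therefore demonstrates correctness of the estimators under
the stated model, not performance guarantees on arbitrary real data.

# WSNF clustering

Per kingdom, sample similarity is $1 - \mathrm{BC}$ (Bray–Curtis). The
fusion is standard SNF cross-diffusion: full kernels are row-normalized
with half the mass on the diagonal, sparse kernels keep each sample's `k`
nearest neighbours, and each iteration diffuses one kingdom's kernel
through the weighted average of the others, for 20 iterations (the
SNF-literature default). Kingdom weights are taxonomic richness shares
(retained taxa / total). The weighting enters both inside the diffusion
(partner matrices are weight-averaged) and in the final fused average;
with a single input or a zero-weight partner the kernel is simply
normalized and returned.

The number of clusters comes from the eigengap of the symmetric
normalized Laplacian (search range 2–10; cohort-scale cluster counts are
small), with a warning and the boundary value on degenerate spectra. The
neighbourhood size `k` is selected by mean silhouette width over a grid
(default {5, 10, 15, 20} capped at $n/5$), using $1 -$ fused similarity
as the distance; because the fused kernel is diagonal-dominant this
distance compresses silhouette magnitudes, so silhouettes are compared
across `k` rather than interpreted absolutely. Ties go to the smallest
`k`. Spectral clustering uses row-normalized Laplacian eigenvectors and
seeded k-means with 20 restarts; `nClusters == n` returns singletons
directly since k-means is degenerate there.

# Ensemble co-occurrence inference

Four association measures are computed on the merged relative profile of
one sample group:

* **COAT** (composition-adjusted thresholding): the CLR covariance is
  taken as the basis-covariance estimate and soft-thresholded entrywise
  by $\lambda_{ij} = s\sqrt{\hat\theta_{ij}\ln p / n}$, where
  $\hat\theta_{ij}$ is the empirical variance of the centered
  cross-products and $s = 0.2$; the result is reported as a correlation.
  The CLR pseudocount defaults to half the smallest nonzero relative
  abundance.
* **Sparse graph**: Meinshausen–Bühlmann neighbourhood selection
  (node-wise lasso via `glmnet`) on the CLR scale over a 100-penalty
  log-spaced path, with the penalty chosen by StARS (20 subsamples of
  80%, total-instability target 0.05). Edge scores are signed
  symmetrized coefficients. Neighbourhood selection is used because it is
  the established, numerically robust sparse-graph estimator available in
  this dependency set; its symmetrized coefficients play the role of
  partial correlations.
* **Mutual information**: plug-in MI (nats) on equal-frequency bins
  (default $\lfloor\sqrt n\rfloor$ capped at 10). Magnitude-only.
* **Bray–Curtis association**: $1 - \mathrm{BC}$ between taxon vectors,
  so that for every member a larger score means a stronger association.
  Magnitude-only.

## Significance: bootstrap scores, permutation p-values

`rebootEdgePvalues()` separates two concerns:

* the **reported score** of a pair is the mean of the member's score over
  100 bootstrap resamplings of the samples (columns re-closed each time),
  which stabilizes both magnitude and sign — for the sparse member this
  acts like stability selection and markedly improves edge ranking;
* the **p-value** compares the member's *test statistic on the full
  data* against a permutation null in which every taxon's values are
  independently shuffled across samples and the composition re-closed.
  This is the standard permutation-test comparison; estimator biases
  (e.g. the plug-in MI bias) appear identically in the observed and null
  terms and cancel.

Comparing a bootstrap-*averaged* observed value against single-recompute
nulls was evaluated and rejected: bootstrap duplication inflates plug-in
MI far above any full-sample null (every pair "significant"), and
hard-thresholded or lasso-selected statistics have an atom at zero that
puts point mass at $p = 1$. For the same reason the two regularized
members test smooth surrogates: COAT tests its unthresholded CLR
correlation, and the sparse member tests a ridge-regularized CLR partial
correlation (ridge $0.3\times$ the mean covariance diagonal — strong
enough to be stable under collinearity, conditional enough to remain a
partial-correlation-type statistic).

The null for COAT, MI and Bray–Curtis shuffles one endpoint of each pair
(the lower-indexed taxon) with efficient per-row updates; the joint
sparse-graph fit cannot be updated per endpoint at acceptable cost and
uses the all-rows-shuffled null. For MI and Bray–Curtis the composition
is not re-closed inside the null: re-closing an already-closed matrix
after shuffling one row shrinks that row's spikes and makes the null
systematically conservative (this was measured, not guessed).

Calibration, verified on "label-free" data (a cohort whose taxon rows
are decoupled by permutation and re-closed): COAT, sparse-graph and MI
p-values are uniform by a Kolmogorov–Smirnov check. The Bray–Curtis
member remains mildly conservative on compositional data because closure
couples taxa negatively — observed cross-taxon similarity sits slightly
below any alignment-permutation null. This is a structural property of
similarity measures on closed data, not an implementation artifact; its
practical effect is a conservative contribution to the merged p-value.

## Aggregation

Per method the absolute scores are min–max normalized over pairs; the
aggregate score is their (by default equal-) weighted mean. The edge sign
comes from the two sign-bearing members: agreement (or a single defined
sign) decides; a conflict excludes the edge (merged p forced to 1), with
an optional "larger normalized magnitude wins" rule. Merged p-values use
the weighted Simes combination
$\min_i \big(\sum_j w_j\big) p_{(i)} / \sum_{j\le i} w_{(j)}$, equal
weights by default at the edge level. Networks keep edges with merged
$p$ strictly below the threshold; 1e-3 is the strict preset and 0.01 the
laxer one. Note the resampling floor: with $B$ permutations no member
p-value can fall below $1/(B+1)$, so the 1e-3 preset requires
$B \ge 999$; under the reduced 100-permutation preset use 0.01.

# Robustness and keystones

Natural connectivity is $\ln\frac1N\sum_i e^{\lambda_i}$ over adjacency
eigenvalues of the unsigned network skeleton (log-sum-exp stabilized),
normalized by $N - \ln N$ so different-sized remainders are comparable;
the normalization constant follows from the complete graph bounding the
measure. Signs enter only through the negative-edge subnetwork analysis.
Random attacks remove uniform node subsets of size 1..N-1, by default
1000 repetitions per size; group comparison applies a two-sided Wilcoxon
rank-sum test per removal count and merges the p-values by weighted
Simes with the number of remaining nodes as weight, so early attack
stages dominate. Identical samples give p = 1 by convention. A caveat
for size normalization: very small subnetworks are mechanically "dense"
(a 3-edge, 5-node graph outranks a 34-edge, 28-node one), so negative-only
comparisons are meaningful when both negative subnetworks span a
substantial node set.

IVI combines degree, ClusterRank, neighbourhood connectivity, local
H-index, betweenness and collective influence, each min–max scaled to
[1, 100] (constant components map to 100 — all nodes equally
influential); hubness and spreading combine as products and the result is
rescaled to [1, 100]. Keystone detection removes nodes cumulatively in
decreasing-IVI order (ties broken by node id) and compares the
connectivity trajectory against random removal orders. The per-prefix
p-value uses the midpoint rule — strict exceedances plus half of ties,
with a 1e-9 tolerance so eigensolver noise cannot turn a same-node-set
null into an exceedance. Ties are structural: a random order removes the
targeted node first with probability $1/N$, so the first prefix's
p-value has a floor near $1/(2N)$ and `alpha` must exceed it; toy-scale
analyses use `alpha = 0.05`, and the stringent 0.001 convention is
reachable only for networks of several hundred nodes. The keystone set
is the maximal initial prefix significant at every step.

# Reproducibility

Every stochastic stage takes an explicit seed; the pipeline derives
stage seeds deterministically from one global seed, so stages re-run in
isolation reproduce the pipeline run. Test-suite problem sizes are
deliberately scaled down (cohorts of 30–80 taxa and 100–500 samples per
group, 100–200 resampling repetitions); the full 1000/1000 attack and
permutation presets match the intended field use.

# Known limitations

* The Bray–Curtis member's p-values are conservative on compositional
  data (see above); the ensemble's merged p inherits a conservative
  tilt from it.
* The sparse-graph permutation null reshuffles all taxa jointly, so on
  strongly structured data its p-values are approximate.
* Natural-connectivity normalization makes tiny subnetworks look robust;
  interpret negative-only comparisons only when the negative subnetworks
  are of comparable, non-trivial size.
* The keystone permutation test cannot certify significance below the
  structural tie floor ~1/(2N).
* Weighted Simes is valid under positive dependence; per-size attack
  samples are positively dependent across removal counts, which is the
  intended regime, but the merged p is not an exact error rate.
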