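---
title: "Cross-modal manifold alignment of paired single-cell data: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modal manifold alignment of paired single-cell data: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchalign)
```

## The problem

Patch-seq measures gene expression and electrophysiology in the *same*
neuron, so an experiment yields two feature matrices over the same n cells:
an electrophysiology matrix $X_e$ (n cells $\times$ $d_1$ e-features) and an
expression matrix $X_t$ (n cells $\times$ $d_2$ genes), with a known
one-to-one correspondence between their rows. The two views are very
different measurements of one underlying cell state, and the relationship
between them is in general nonlinear. patchalign co-embeds both views on a
shared low-dimensional latent space so that (i) corresponding cells land
close together, (ii) each view's local neighbourhood structure is
preserved, and (iii) downstream analyses — clustering, marker detection,
cross-modal prediction — can operate on a single representation supported
by both modalities.

## The alignment model

Let $W_e$ and $W_t$ be binary k-nearest-neighbour graphs built within each
modality, and let $C$ be the cross-modal correspondence matrix (the
identity when every cell's pairing is known; a partial identity in the
semi-supervised setting). We seek embeddings
$\tilde X_e, \tilde X_t \in \mathbb{R}^{n\times d}$ minimising

$$
\mu \sum_{ij} W_e^{ij}\,\lVert \tilde x_e^i - \tilde x_e^j \rVert^2
+ \mu \sum_{ij} W_t^{ij}\,\lVert \tilde x_t^i - \tilde x_t^j \rVert^2
+ (1-\mu) \sum_{ij} C^{ij}\,\lVert \tilde x_e^i - \tilde x_t^j \rVert^2 ,
$$

subject to the non-degeneracy constraint $Q^\top D Q = I$, where
$Q = [\tilde X_e; \tilde X_t]$ stacks both embeddings. Writing the
assembled joint graph

$$
W = \begin{pmatrix} \mu W_e & (1-\mu)\,C \\ (1-\mu)\,C^\top & \mu W_t
\end{pmatrix},\qquad D = \mathrm{diag}(W\mathbf 1),\qquad L = D - W,
$$

the objective is the quadratic form $\mathrm{tr}(Q^\top L Q)$ (the package
records this form, in which cross-modal pairs are counted in both orders —
a factor-of-two bookkeeping on the cross term that does not change the
minimiser), and the solution is given by the generalized eigenproblem
$L v = \lambda D v$: the d eigenvectors with the smallest *non-trivial*
eigenvalues, split into the e-rows and t-rows. This is the classical
Laplacian-eigenmap construction extended with a correspondence coupling:

* **NMA** (nonlinear manifold alignment) solves the problem directly over
  free coordinates. It is nonparametric: it returns coordinates for the
  training cells and has no out-of-sample map.
* **LMA** (linear manifold alignment) restricts $\tilde X_e = X_e f$,
  $\tilde X_t = X_t g$ and solves the projected pencil
  $Z^\top L Z\,u = \lambda\, Z^\top D Z\,u$ with
  $Z = \mathrm{blockdiag}(X_e, X_t)$; it returns projection matrices that
  can embed held-out cells. Because linear maps are a subset of free
  embeddings, the LMA optimum can never beat the NMA optimum on the same
  joint graph — a property the test suite asserts.
* **CCA**, **RRR** (reduced-rank regression of $X_e$ on $X_t$) and
  per-modality **PCA** (no alignment at all) are included as the standard
  linear baselines and controls.

All five run through one fitting function, `manifold_align()`, which
returns a classed object with `print`, `summary`, `coef`, `predict` and
`plot` methods.

### Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `k` | 2 | intra-modal kNN neighbours. Small k preserves fine manifold structure; the default follows the upstream analyses this package models. |
| `d` | 3 | latent dimension; 3 supports visualisation and is where the alignment metrics flatten. |
| `mu` | 0.5 | trade-off between manifold preservation and correspondence pull; 0.5 weighs them equally, which also makes scores comparable with unsupervised aligners. |
| `eig_tol` | 1e-8 | eigenvalues at or below this are trivial (constant on a connected component) and are discarded — one per component, so disconnected joint graphs are handled by the threshold rather than by a fixed count. |

kNN construction details that the tests pin down: self is excluded,
distance ties are broken toward the lower cell index (determinism), and the
directed relation is symmetrized by union, which keeps graphs connected at
small k. Weighted (heat-kernel) edges are available but off by default; the
binary graph is the documented convention.

## Evaluating an alignment

* **Paired distances**: the Euclidean distance between a cell's two
  embeddings. For cross-method comparison each row of the stacked
  $2n \times d$ coordinate matrix is z-scored first (methods differ
  arbitrarily in latent scale); the unstandardized variant is a flag.
  With d = 1 a row z-score is undefined and standardization errors.
* **FOSCTTM** (fraction of samples closer than the true match): for each
  cell, the fraction of the other modality's cells strictly closer than
  the cell's true partner, averaged over cells and both directions
  (one-direction means are also reported). 0 is perfect; ~0.5 is what
  random placement gives — the suite checks both ends and the isometry
  invariance of the score. Ties count as "not closer".
* **Silhouette widths** of external labels on the latent space
  (singleton labels get width 0, via the standard implementation in the
  cluster package).
* **Semi-supervised protocol**: keep a seeded random fraction of the
  correspondences (half, in the study conditions), align, and score
  paired distances and FOSCTTM on the held-out cells only.

## Cross-modal clusters

Clustering operates on the combined feature set $[\tilde X_e, \tilde X_t]$
(n cells $\times$ 2d), so a cluster must be supported by both views. The
model is a full-covariance Gaussian mixture fitted by EM with k-means++
seeded initialization, at most 100 iterations, relative log-likelihood
tolerance 1e-8, and a covariance floor of 1e-6 times the mean feature
variance added to each diagonal. The floor is *relative* because
D-orthonormal eigenmap coordinates are numerically tiny (order 1e-2 at
n = 500); an absolute floor of comparable magnitude to the data variance
would distort the M-step and break EM's monotone log-likelihood, which the
implementation asserts at the same relative tolerance. Cells are assigned
to the maximum-posterior component (computed in log space; ties to the
lower index).

The number of components is chosen by BIC
($p\ln n - 2\ln\hat L$, with $p = K-1 + Kd' + Kd'(d'+1)/2$ free
parameters) over `K_range`, each K taking the best of 5 seeded EM
restarts. The selection rule is the *elbow*, not the argmin: the smallest
K after which the next BIC improvement falls below 5% of the BIC range
(argmin is the fallback and is always reported alongside). The rationale
is visible in this package's own latents: eigenmap clusters are curved,
slightly heavy-tailed filaments rather than Gaussians, so past the true
cluster number extra components keep paying for cluster *shape* with
small, steady BIC gains. The argmin then drifts upward (and, at a fixed
K, the likelihood can genuinely prefer one diffuse "halo" component
absorbing all clusters' tails — a known pathology of maximum-likelihood
mixtures on non-Gaussian clusters), while the flattening point of the BIC
curve tracks the planted cluster number reliably. PAM k-medoids and
average-linkage hierarchical clustering are provided as robustness checks,
and `cluster_label_concordance()` reports the contingency table,
per-label best-cluster fractions and the adjusted Rand index against any
external labelling.

## Markers and representative e-features

Differential features are tested one-vs-rest per cluster with the
two-sided Wilcoxon rank-sum test: exact by enumeration of all
$\binom{n}{n_1}$ arrangements when both groups have at most 10 cells
(two-sided by distance of the rank sum from its permutation mean, which
handles ties exactly), otherwise the normal approximation with
tie-corrected variance and no continuity correction. The AUC is reported
as $U/(n_1 n_2)$ and equals the rank-sum effect size identically.
P-values are Benjamini–Hochberg adjusted across features within a
cluster; markers are features with adjusted p strictly below the
threshold (0.01 by default) *and* positive shift. Representative
electrophysiological features run the same machinery on the absolute
values of the standardized e-features (threshold 0.05), so a feature
whose magnitude distinguishes a cluster in either direction is flagged.
No detection-fraction or fold-change pre-filters are applied by default;
both exist as options.

## Prediction

* `latent_regression()`: closed-form OLS
  $\hat B = (\tilde X_t^\top \tilde X_t)^{-1}\tilde X_t^\top \tilde X_e$,
  no intercept (latent components are near-centred by construction).
* `cv_r2()`: 10-fold cross-validation with 20 repetitions;
  $R^2 = 1 - \lVert \tilde X_e^{test} - \tilde X_t^{test}\hat B\rVert^2 /
  \lVert \tilde X_e^{test}\rVert^2$ with both held-out blocks centred by
  their own means, averaged over folds and repetitions.
* `predict_efeature_from_degs()`: a single e-feature regressed (with
  intercept, since raw expression is not centred — a documented divergence
  from the latent-space formula) on a cluster's differential genes over
  all cells, with a seeded 90/10 train/test split; train and test $R^2$
  are taken about the respective split's mean.
* `feature_latent_correlations()`: Pearson correlations of each original
  feature with the first three latent components of its own modality; for
  each biplot plane the radius $\sqrt{r_a^2 + r_b^2}$ is reported and
  features with radius strictly above 0.6 are flagged for display.

## The synthetic generator

`simulate_patchseq()` generates the paired views every test runs on. Cells
sit on a 1-D latent trajectory in $[0,1]$ cut into K contiguous arcs
(clusters); a cell's position is its arc centre plus Gaussian jitter, with
arc centres `separation` within-cluster standard deviations apart
(default 6 — the planted analogue of clearly distinguishable inhibitory
classes; the spacing definition makes "separation" a measurable quantity).
The electrophysiology view applies per-feature smooth maps (random-phase
sinusoids by default; cubics and linear maps are options) to the
trajectory plus Gaussian noise. The expression view has three gene groups:

* **markers** — pure noise plus an up-shift of `marker_shift` noise
  standard deviations inside their own cluster (absolute units when the
  noise is zero), disjoint sets per cluster, recorded in the ground truth;
* **phase genes** — each gene applies its smooth map to the standardized
  within-arc offset with an independent random sign per cluster. The
  offset is N(0,1) in every cluster, so every phase gene has an
  *identical* value distribution across clusters: the planted markers are,
  by construction, the only cluster-differential genes, which is what
  makes marker precision/recall against the ground truth meaningful. The
  per-cluster signs ensure no two clusters share an expression signature
  (an earlier construction with period-aligned maps made same-offset cells
  of different clusters exactly equivalent, which leaks aliased kNN edges
  and heavy embedding tails);
* the remainder, if any — pure noise.

One e-feature is planted to be predictable: a standardized linear
combination of five designated genes' rendered expression carrying 80% of
the feature's variance by default (the noise share is exact by
construction, so regression recovery targets are well defined). Expression
is simulated directly on log scale — Gaussian around smooth signal — which
keeps effect sizes in sd units; count-level noise (dropout, library size),
realistic spike statistics, batch structure and doublets are deliberately
out of scope. Passing tests therefore demonstrate correctness of the
computations and recoverability under a clean two-view manifold model, not
robustness to the full noise anatomy of real Patch-seq data.

All randomness flows from one integer seed; the seed is recorded in the
`truth.json` sidecar that `write_synthetic()` emits.

## Numerical choices

* Dense symmetric eigensolvers throughout (whitening by $D^{-1/2}$, or by
  the constraint matrix's inverse square root on its numerical column
  space for LMA). Exact and fast at the scales this package targets
  (seconds at 2n = 1000, minutes at the largest published Patch-seq
  cohorts); no iterative sparse path is provided.
* A rank-deficient LMA constraint matrix is handled by restricting the
  pencil to its column space — flooring instead would admit 0/0
  directions that masquerade as near-zero-loss embeddings.
* Deterministic per-column sign convention (largest-magnitude entry
  positive) so repeated runs agree exactly; tests that compare embeddings
  do so through losses and distances, never raw coordinates, since any
  rotation within a degenerate eigenspace is equally valid.
* CCA and RRR add a 1e-6 ridge when covariances are singular
  (expression panels can exceed the cell count); the event is reported.
* kNN ties, posterior ties and marker thresholds all break
  deterministically (lower index / strict inequality), so a fixed seed
  reproduces every artifact byte for byte — the pipeline writes a
  manifest with checksums to make that checkable.

## Problem sizes in the test suite

The suite exercises the full pipeline at n = 500 cells, K = 5 clusters,
30 e-features and 100 genes (the generator defaults), with smaller
instances (n ≤ 30) for the brute-force oracle comparisons and n = 150 for
the byte-identity pipeline runs. These sizes were chosen so that exact
oracles (dense eigendecompositions, exhaustive rank-sum enumeration,
exhaustive eigenvector subsets) remain feasible while the study-scale
behaviour is still visible.

## Known limitations

* NMA has no out-of-sample extension; use LMA or the linear baselines
  when held-out cells must be projected.
* At a fixed K, the maximum-likelihood GMM solution on eigenmap latents
  can be the tail-absorbing "halo" configuration described above; the
  elbow-selected K together with k-means++-seeded restarts avoids it in
  practice, but likelihood alone is not a reliable arbiter of cluster
  quality on such geometry.
* k = 2 graphs are fragile: a single aliased edge can distort the local
  embedding. Raising k trades fine structure for robustness.
* The dense solver's memory grows as $(2n)^2$; beyond a few thousand
  cells per modality an iterative eigensolver would be needed.
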