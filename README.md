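# patchalign

Cross-modal manifold alignment of paired single-cell transcriptomic and
electrophysiological data.

Patch-seq experiments record gene expression and electrophysiology in the
*same* neurons, producing two feature matrices over the same n cells — an
e-feature matrix X<sub>e</sub> (n × d₁) and an expression matrix
X<sub>t</sub> (n × d₂) — with a known one-to-one row correspondence. The
relationship between the two views is nonlinear, so linear joint analyses
leave much of it on the table. patchalign is for analysts of such paired
multimodal data who want a single latent representation of each cell
supported by both measurements.

## The method

The core is manifold alignment: build a binary kNN graph per modality
(W<sub>e</sub>, W<sub>t</sub>), couple them through the correspondence
matrix C, and minimise

> μ Σᵢⱼ W<sub>e</sub>ⁱʲ‖x̃<sub>e</sub>ⁱ − x̃<sub>e</sub>ʲ‖² +
> μ Σᵢⱼ W<sub>t</sub>ⁱʲ‖x̃<sub>t</sub>ⁱ − x̃<sub>t</sub>ʲ‖² +
> (1−μ) Σᵢⱼ Cⁱʲ‖x̃<sub>e</sub>ⁱ − x̃<sub>t</sub>ʲ‖²

subject to QᵀDQ = I, where Q stacks both embeddings and D is the joint
graph's degree matrix. The solution is the bottom non-trivial eigenvectors
of the generalized problem L v = λ D v (a Laplacian eigenmap with
cross-modal coupling). Nonlinear alignment (NMA) solves for free
coordinates; linear alignment (LMA) restricts to linear projections; CCA,
reduced-rank regression and per-modality PCA are included as baselines.
Downstream, the package evaluates alignments (per-cell paired distances,
FOSCTTM), clusters cells on the combined latent features with a Gaussian
mixture selected by BIC, detects per-cluster marker genes (Wilcoxon
rank-sum + Benjamini–Hochberg) and representative e-features, and predicts
electrophysiology from expression by closed-form multivariate regression
with cross-validated R². A synthetic paired-view generator with recorded
ground truth (clusters, markers, a predictable e-feature) makes the whole
pipeline testable offline. See `vignettes/cross-modal-alignment.Rmd` for
the full methods account.

## Worked example

```r
library(patchalign)

# paired views of 500 cells in 5 clusters from a shared 1-D trajectory
ds <- simulate_patchseq(synth_config(seed = 1))
ds <- mm_dataset(standardize_features(ds$e), standardize_features(ds$t),
                 ds$labels)

fit <- manifold_align(ds, "nma")    # k = 2, d = 3, mu = 0.5
summary(fit)
#> NMA alignment of 500 cells (d = 3)
#>   mean paired distance (standardized): 0.0359
#>   mean FOSCTTM: 0.0261
#>   embedding loss: 0.0072641
```

A mean FOSCTTM of 0.026 means that, on average, only ~2.6% of cells sit
closer to a cell's latent position than its own measurement from the other
modality (0 is perfect, 0.5 is random); the PCA control on the same data
gives a standardized paired distance of ~1.9 versus 0.036 here. Clustering
the combined latent features:

```r
feats <- combined_features(fit)
sel <- select_K_bic(feats, 1:8, seed = 2)   # BIC elbow -> K = 5
asg <- assign_clusters(sel$fits[[match(sel$K, sel$bic_table$K)]], feats)
asg
#> cluster_assignment: 500 cells in 5 clusters
#>   1   2   3   4   5
#> 107  99 104  95  95
cluster_label_concordance(asg, ds$labels)$ari
#> [1] 0.9900912
```

The recovered clusters match the generator's planted partition (ARI 0.99),
and marker detection returns the planted marker genes per cluster:

```r
tab <- wilcoxon_de_all(ds$t, asg, alpha = 0.01)
select_markers(tab, 0.01)$cluster2
#> [1] "g001" "g002" "g003" "g004" "g005"
```

`run_pipeline(pipeline_config(synthetic = synth_config(seed = 1)))` runs
simulate → preprocess → align → evaluate → cluster → markers → predict in
one call and writes every artifact with a checksummed manifest; the same
seed reproduces the bundle byte for byte.

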