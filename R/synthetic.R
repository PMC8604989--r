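#' Configuration for the synthetic paired-view generator
#'
#' The generator emulates a Patch-seq style experiment: the same cells are
#' measured in two modalities, both views are smooth (possibly nonlinear)
#' images of a shared low-dimensional latent trajectory with cluster
#' structure, each cluster carries planted marker genes, and one
#' electrophysiological feature is constructed to be predictable from a
#' designated gene set.
#'
#' Cells live on a 1-D trajectory in `[0, 1]` split into `n_clusters`
#' contiguous arcs; a cell's position is its arc centre plus Gaussian
#' within-cluster jitter whose standard deviation is set so that adjacent
#' arc centres are `separation` within-cluster standard deviations apart.
#' Expression features fall into three groups: `n_clusters *
#' n_markers_per_cluster` marker genes (pure noise plus a `marker_shift`
#' up-shift inside their cluster), "phase" genes that encode the fine-scale
#' position along the cell's own arc through smooth maps with a per-cluster
#' random sign (so their value distribution is identical across clusters and
#' only the markers are cluster-differential), and the remainder pure noise.
#' Electrophysiological features are smooth maps of the trajectory; the
#' last one is replaced by a noisy linear combination of the designated
#' genes' rendered expression (the planted predictable e-feature).
#'
#' @param n_cells number of cells (default 500).
#' @param n_clusters number of planted clusters (default 5).
#' @param d1 number of electrophysiological features (default 30).
#' @param d2 number of genes (default 100).
#' @param latent_dim intrinsic dimension of the shared manifold (default 1;
#'   higher values draw additional independent uniform coordinates used by
#'   the view maps, without cluster structure).
#' @param noise_sd_e,noise_sd_t additive Gaussian noise standard deviations
#'   per view (defaults 0.2 and 1).
#' @param marker_shift per-cluster marker effect, in units of
#'   `noise_sd_t` (default 3).
#' @param n_markers_per_cluster planted markers per cluster (default 5).
#' @param n_phase_genes genes carrying the cluster-balanced within-arc
#'   trajectory signal (default: all non-marker genes).
#' @param nonlinearity view map family: `"sinusoidal"` (default),
#'   `"polynomial"` (random cubics) or `"linear"`.
#' @param separation distance between adjacent cluster centres in
#'   within-cluster standard deviations (default 6).
#' @param n_pred_genes designated predictor genes for the planted
#'   predictable e-feature (default 5).
#' @param pred_noise_frac fraction of the planted e-feature's variance that
#'   is noise (default 0.2).
#' @param seed integer seed; all randomness flows from it.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_cells = 500, n_clusters = 5, d1 = 30, d2 = 100,
                         latent_dim = 1, noise_sd_e = 0.2, noise_sd_t = 1,
                         marker_shift = 3, n_markers_per_cluster = 5,
                         n_phase_genes = NULL,
                         nonlinearity = c("sinusoidal", "polynomial",
                                          "linear"),
                         separation = 6, n_pred_genes = 5,
                         pred_noise_frac = 0.2, seed = 1) {
  nonlinearity <- match.arg(nonlinearity)
  n_markers <- n_clusters * n_markers_per_cluster
  if (is.null(n_phase_genes)) n_phase_genes <- d2 - n_markers
  cfg <- list(n_cells = n_cells, n_clusters = n_clusters, d1 = d1, d2 = d2,
              latent_dim = latent_dim, noise_sd_e = noise_sd_e,
              noise_sd_t = noise_sd_t, marker_shift = marker_shift,
              n_markers_per_cluster = n_markers_per_cluster,
              n_phase_genes = n_phase_genes, nonlinearity = nonlinearity,
              separation = separation, n_pred_genes = n_pred_genes,
              pred_noise_frac = pred_noise_frac, seed = as.integer(seed))
  stopifnot(cfg$n_cells >= cfg$n_clusters, cfg$n_clusters >= 1,
            cfg$d1 >= cfg$latent_dim, cfg$d2 >= cfg$latent_dim,
            cfg$noise_sd_e >= 0, cfg$noise_sd_t >= 0,
            n_markers + cfg$n_phase_genes <= cfg$d2,
            cfg$n_pred_genes <= cfg$n_phase_genes || cfg$n_pred_genes == 0,
            cfg$pred_noise_frac >= 0, cfg$pred_noise_frac < 1)
  class(cfg) <- "synth_config"
  cfg
}

#' Draw the latent trajectory and cluster labels
#'
#' Cells are assigned to `n_clusters` contiguous arcs of `[0, 1]` by a
#' uniform draw, then positioned at their arc centre plus Gaussian jitter
#' (sd = arc spacing / `separation`). Deterministic given `config$seed`.
#'
#' @param config a [synth_config].
#' @return a `synth_truth` list with `latent_positions` (n x latent_dim
#'   matrix), `cluster_labels` (integers 1..K), `cluster_centers`, and
#'   placeholders filled in by [render_views()].
#' @export
generate_latent <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_cells
  K <- config$n_clusters
  u <- stats::runif(n)
  labels <- pmin(ceiling(u * K), K)
  labels[labels < 1] <- 1L
  centers <- (seq_len(K) - 0.5) / K
  sigma_w <- if (K > 1) (1 / K) / config$separation else 0.25 / config$separation
  s <- centers[labels] + stats::rnorm(n, 0, sigma_w)
  latent <- matrix(s, ncol = 1)
  if (config$latent_dim > 1)
    latent <- cbind(latent,
                    matrix(stats::runif(n * (config$latent_dim - 1)),
                           nrow = n))
  colnames(latent) <- paste0("z", seq_len(config$latent_dim))
  structure(list(latent_positions = latent,
                 cluster_labels = as.integer(labels),
                 cluster_centers = centers, within_sd = sigma_w,
                 marker_sets = NULL, predictable_map = NULL,
                 correspondence = seq_len(n), seed = config$seed),
            class = "synth_truth")
}

# smooth per-feature map of the primary latent coordinate
smooth_map <- function(s, n_features, nonlinearity, rng_amp = c(0.6, 1.4)) {
  n <- length(s)
  vapply(seq_len(n_features), function(j) {
    a <- stats::runif(1, rng_amp[1], rng_amp[2])
    switch(nonlinearity,
           linear = a * s,
           sinusoidal = {
             omega <- stats::runif(1, 0.75, 2.5) * pi
             phi <- stats::runif(1, 0, 2 * pi)
             a * sin(omega * s + phi)
           },
           polynomial = {
             co <- stats::rnorm(3)
             x <- 2 * s - 1
             a * (co[1] * x + co[2] * x^2 + co[3] * x^3)
           })
  }, numeric(n))
}

#' Render the two observed views from the latent truth
#'
#' See [synth_config()] for the generative model. The electrophysiology
#' view is a smooth map of the trajectory plus noise; the expression view
#' combines cluster-balanced within-arc phase genes, planted per-cluster
#' marker genes and pure-noise genes. The last e-feature is replaced by the
#' planted predictable feature: a standardized linear combination of the
#' designated phase genes' rendered expression carrying
#' `1 - pred_noise_frac` of the feature's variance.
#'
#' @param truth a `synth_truth` from [generate_latent()] (modified in the
#'   returned attribute `truth`).
#' @param config the same [synth_config].
#' @return an [mm_dataset] with attribute `"truth"` holding the completed
#'   `synth_truth` (marker sets, predictable map, labels).
#' @export
render_views <- function(truth, config) {
  stopifnot(inherits(truth, "synth_truth"), inherits(config, "synth_config"))
  set.seed(config$seed + 1L)
  n <- config$n_cells
  K <- config$n_clusters
  s <- truth$latent_positions[, 1]
  labels <- truth$cluster_labels
  gene_names <- sprintf("g%03d", seq_len(config$d2))
  e_names <- sprintf("ef%02d", seq_len(config$d1))

  ## electrophysiology view: smooth maps of the trajectory
  e_signal <- smooth_map(s, config$d1, config$nonlinearity)
  if (config$latent_dim > 1)
    for (l in 2:config$latent_dim)
      e_signal <- e_signal +
        0.5 * smooth_map(truth$latent_positions[, l], config$d1,
                         config$nonlinearity)

  ## expression view
  n_markers <- K * config$n_markers_per_cluster
  t_signal <- matrix(0, n, config$d2)
  phase_idx <- seq(n_markers + 1, length.out = config$n_phase_genes)
  ## phase genes encode the position along the cell's own arc. The
  ## standardized within-arc offset u is N(0,1) in every cluster, and each
  ## gene flips its sign independently per cluster before applying its
  ## smooth map, so the value distribution is identical across clusters
  ## (only planted markers are cluster-differential) while within-cluster
  ## neighbourhoods still follow the trajectory and no two clusters share
  ## an expression signature.
  u <- (s - truth$cluster_centers[labels]) /
    max(truth$within_sd, .Machine$double.eps)
  for (j in phase_idx) {
    a <- stats::runif(1, 0.6, 1.4)
    sgn <- sample(c(-1, 1), K, replace = TRUE)
    z <- sgn[labels] * u
    t_signal[, j] <- a * switch(config$nonlinearity,
      linear = z,
      sinusoidal = sqrt(2) * sin(stats::runif(1, 0.4, 1.2) * z +
                                 stats::runif(1, 0, 2 * pi)),
      polynomial = {
        co <- stats::rnorm(3) / sqrt(3)
        co[1] * z + co[2] * (z^2 - 1) / sqrt(2) + co[3] * z^3 / sqrt(15)
      })
  }
  ## markers: up-shift in their own cluster only; the shift is expressed
  ## in units of the expression noise sd (absolute when that sd is zero)
  shift <- config$marker_shift *
    (if (config$noise_sd_t > 0) config$noise_sd_t else 1)
  marker_sets <- vector("list", K)
  names(marker_sets) <- paste0("cluster", seq_len(K))
  for (k in seq_len(K)) {
    cols <- (k - 1) * config$n_markers_per_cluster +
      seq_len(config$n_markers_per_cluster)
    t_signal[labels == k, cols] <- t_signal[labels == k, cols] + shift
    marker_sets[[k]] <- gene_names[cols]
  }

  e_vals <- e_signal + matrix(stats::rnorm(n * config$d1, 0,
                                           config$noise_sd_e), n)
  t_vals <- t_signal + matrix(stats::rnorm(n * config$d2, 0,
                                           config$noise_sd_t), n)

  ## planted predictable e-feature: a standardized linear combination of
  ## the designated genes' rendered expression plus Gaussian noise carrying
  ## exactly pred_noise_frac of the feature's variance. Planting on the
  ## observed expression makes the noise-share semantics exact for a
  ## linear expression -> e-feature regression.
  predictable_map <- NULL
  if (config$n_pred_genes > 0 && config$d1 >= 1) {
    pred_genes <- phase_idx[seq_len(config$n_pred_genes)]
    beta <- stats::runif(config$n_pred_genes, 0.5, 1.5) *
      sample(c(-1, 1), config$n_pred_genes, replace = TRUE)
    ysig <- drop(t_vals[, pred_genes, drop = FALSE] %*% beta)
    ysig <- (ysig - mean(ysig)) / stats::sd(ysig)
    q <- config$pred_noise_frac
    e_vals[, config$d1] <- sqrt(1 - q) * ysig +
      stats::rnorm(n, 0, sqrt(q))
    predictable_map <- list(genes = gene_names[pred_genes],
                            e_feature = e_names[config$d1],
                            coefficients = beta, noise_frac = q)
  }

  cell_ids <- sprintf("cell%04d", seq_len(n))
  e <- feature_matrix(e_vals, cell_ids, e_names, "electrophysiology")
  t <- feature_matrix(t_vals, cell_ids, gene_names, "expression")
  labels_chr <- stats::setNames(paste0("type", labels), cell_ids)
  ds <- mm_dataset(e, t, labels_chr)
  truth$marker_sets <- marker_sets
  truth$predictable_map <- predictable_map
  attr(ds, "truth") <- truth
  ds
}

#' Generate a complete synthetic paired dataset
#'
#' Convenience wrapper: [generate_latent()] followed by [render_views()].
#'
#' @param config a [synth_config]; or arguments passed to [synth_config()].
#' @param ... passed to [synth_config()] when `config` is missing.
#' @return an [mm_dataset] with attribute `"truth"`.
#' @export
simulate_patchseq <- function(config = synth_config(...), ...) {
  render_views(generate_latent(config), config)
}

#' Write a synthetic dataset and its ground truth to a directory
#'
#' Writes `e.csv`, `t.csv`, `labels.tsv` and a `truth.json` sidecar
#' (cluster labels, marker sets, predictable map, seed).
#'
#' @param ds an [mm_dataset] carrying a `"truth"` attribute.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_matrix(ds$e, file.path(dir, "e.csv"))
  write_feature_matrix(ds$t, file.path(dir, "t.csv"))
  if (!is.null(ds$labels))
    utils::write.table(data.frame(cell_id = names(ds$labels),
                                  label = unname(ds$labels)),
                       file.path(dir, "labels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  truth <- attr(ds, "truth")
  if (!is.null(truth)) {
    truth$latent_positions <- unname(apply(truth$latent_positions, 1, c,
                                           simplify = FALSE))
    jsonlite::write_json(truth[c("cluster_labels", "marker_sets",
                                 "predictable_map", "seed",
                                 "latent_positions")],
                         file.path(dir, "truth.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(dir)
}
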