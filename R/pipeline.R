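#' End-to-end pipeline configuration
#'
#' Exactly one of `input_dir` (a directory holding `e.csv`, `t.csv` and
#' optionally `labels.tsv` in the package's file conventions) or
#' `synthetic` (a [synth_config]) must be given. All stage seeds are
#' derived from `seed` by fixed offsets so one integer reproduces the
#' whole run.
#'
#' @param input_dir directory with input matrices, or `NULL`.
#' @param synthetic a [synth_config], or `NULL`.
#' @param alignment an [alignment_config] (default NMA, k = 2, d = 3,
#'   mu = 0.5).
#' @param K_range candidate cluster numbers for BIC selection (default 1:8).
#' @param marker_alpha adjusted-p threshold for marker genes (default 0.01).
#' @param efeature_alpha threshold for representative e-features
#'   (default 0.05).
#' @param train_frac train fraction for e-feature prediction (default 0.9).
#' @param out_dir output directory.
#' @param seed global seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL, synthetic = NULL,
                            alignment = alignment_config(),
                            K_range = 1:8, marker_alpha = 0.01,
                            efeature_alpha = 0.05, train_frac = 0.9,
                            out_dir = tempfile("patchalign_run"),
                            seed = 1L) {
  if (is.null(input_dir) == is.null(synthetic))
    stop("give exactly one of input_dir or synthetic")
  structure(list(input_dir = input_dir, synthetic = synthetic,
                 alignment = alignment, K_range = K_range,
                 marker_alpha = marker_alpha,
                 efeature_alpha = efeature_alpha, train_frac = train_frac,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

num_fmt <- function(x) format(x, digits = 15, trim = TRUE, scientific = TRUE)

write_num_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], num_fmt)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
}

#' Run the full cross-modal analysis
#'
#' Stages: load or simulate -> preprocess (log-transform expression when
#' loading raw values is requested, standardize both views) -> align ->
#' evaluate (paired distances, FOSCTTM) -> cluster (BIC-selected GMM on
#' the combined latent features) -> markers (per-cluster genes and
#' representative e-features) -> predict (latent cross-modal regression
#' and, when markers exist, best-cluster e-feature prediction). Every
#' numeric artifact is written to `config$out_dir` together with a
#' `manifest.json` recording seeds, configuration and file checksums;
#' identical configuration and seed reproduce the bundle byte for byte.
#'
#' @param config a [pipeline_config].
#' @param log_transform_expression log2(x+1)-transform the expression view
#'   before standardization (default `FALSE`; synthetic data are already
#'   log-scale).
#' @return (invisibly) a list with the fitted objects and the paths of the
#'   written artifacts.
#' @export
run_pipeline <- function(config, log_transform_expression = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  ## stage 1: data
  if (!is.null(config$synthetic)) {
    ds <- simulate_patchseq(config$synthetic)
    write_synthetic(ds, file.path(config$out_dir, "data"))
  } else {
    e_path <- file.path(config$input_dir, "e.csv")
    t_path <- file.path(config$input_dir, "t.csv")
    for (p in c(e_path, t_path))
      if (!file.exists(p)) stop("stage load: missing input file ", p)
    e <- read_feature_matrix(e_path, modality = "electrophysiology")
    t <- read_feature_matrix(t_path, modality = "expression")
    lab_path <- file.path(config$input_dir, "labels.tsv")
    labels <- if (file.exists(lab_path)) read_labels(lab_path) else NULL
    ds <- filter_complete(e, t, labels = labels)
  }

  ## stage 2: preprocess
  if (log_transform_expression) ds$t <- log_transform(ds$t)
  ds <- mm_dataset(standardize_features(ds$e), standardize_features(ds$t),
                   ds$labels)

  ## stage 3: align
  fit <- manifold_align(ds, config = config$alignment)
  write_embedding(fit, file.path(config$out_dir, "embedding.csv"))

  ## stage 4: evaluate
  pd <- paired_distance(fit, standardize_per_cell = config$alignment$d > 1)
  fs <- foscttm(fit)
  jsonlite::write_json(list(method = fit$method,
                            mean_paired_distance = pd$mean_paired_distance,
                            mean_foscttm = fs$mean_foscttm,
                            foscttm_by_direction = as.list(fs$mean_by_direction)),
                       file.path(config$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)

  ## stage 5: cluster
  feats <- combined_features(fit)
  sel <- select_K_bic(feats, config$K_range, seed = seed + 100L)
  model <- sel$fits[[match(sel$K, sel$bic_table$K)]]
  assign <- assign_clusters(model, feats)
  write_num_csv(data.frame(cell_id = names(assign$labels),
                           cluster = assign$labels,
                           max_posterior = apply(assign$posteriors, 1, max)),
                file.path(config$out_dir, "clusters.csv"))
  write_num_csv(sel$bic_table, file.path(config$out_dir, "bic.csv"))

  ## stage 6: markers
  markers_tab <- NULL
  efeat_tab <- NULL
  sizes <- table(assign$labels)
  if (length(sizes) >= 2 && min(sizes) >= 3) {
    markers_tab <- wilcoxon_de_all(ds$t, assign, alpha = config$marker_alpha)
    write_marker_table(markers_tab, file.path(config$out_dir, "markers.tsv"))
    efeat_tab <- representative_efeatures(ds$e, assign,
                                          alpha = config$efeature_alpha)
    write_marker_table(efeat_tab, file.path(config$out_dir,
                                            "efeatures.tsv"))
  }

  ## stage 7: predict
  cv <- cv_r2(fit$t_coords, fit$e_coords, seed = seed + 200L)
  pred <- NULL
  if (!is.null(markers_tab) && !is.null(efeat_tab)) {
    marker_sets <- select_markers(markers_tab, config$marker_alpha)
    rep_e <- efeat_tab[efeat_tab$significant & efeat_tab$log_fc > 0, ]
    if (length(marker_sets) > 0 && nrow(rep_e) > 0) {
      k <- rep_e$cluster[which.min(rep_e$adj_p)]
      genes <- marker_sets[[paste0("cluster", k)]]
      feat <- rep_e$feature[rep_e$cluster == k][1]
      if (length(genes) >= 1)
        pred <- predict_efeature_from_degs(ds$t[, genes, drop = FALSE],
                                           unclass(ds$e)[, feat],
                                           train_frac = config$train_frac,
                                           seed = seed + 300L)
    }
  }
  jsonlite::write_json(list(cv_mean_r2 = cv$mean_r2,
                            efeature_prediction = if (is.null(pred)) NULL else
                              list(r2_train = pred$r2_train,
                                   r2_test = pred$r2_test)),
                       file.path(config$out_dir, "prediction.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  ## manifest
  files <- setdiff(list.files(config$out_dir, recursive = TRUE),
                   "manifest.json")
  checksums <- tools::md5sum(file.path(config$out_dir, files))
  names(checksums) <- files
  jsonlite::write_json(list(seed = seed,
                            alignment = unclass(config$alignment),
                            K_selected = sel$K,
                            checksums = as.list(checksums)),
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(dataset = ds, fit = fit, metrics = list(paired = pd,
                                                         foscttm = fs),
                 K = sel$K, model = model, assignment = assign,
                 markers = markers_tab, efeatures = efeat_tab,
                 cv = cv, prediction = pred, out_dir = config$out_dir))
}
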