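## rank-sum machinery -------------------------------------------------------

## two-sided exact p for the Wilcoxon rank-sum by enumeration of all
## C(n, n1) group-1 index sets; handles ties since actual (mid)ranks are
## enumerated. Two-sidedness by distance of the rank sum from its mean.
wilcoxon_exact_p <- function(ranks, idx1) {
  n <- length(ranks)
  n1 <- length(idx1)
  combos <- utils::combn(n, n1)
  sums <- colSums(matrix(ranks[combos], nrow = n1))
  mu <- n1 * mean(ranks)
  obs <- abs(sum(ranks[idx1]) - mu)
  mean(abs(sums - mu) >= obs - 1e-9)
}

## normal approximation with tie correction (no continuity correction)
wilcoxon_normal_p <- function(ranks, idx1) {
  n <- length(ranks)
  n1 <- length(idx1); n2 <- n - n1
  W <- sum(ranks[idx1])
  mu <- n1 * (n + 1) / 2
  ties <- table(ranks)
  sig2 <- n1 * n2 * (n + 1) / 12 -
    n1 * n2 * sum(ties^3 - ties) / (12 * n * (n - 1))
  if (sig2 <= 0) return(1)
  2 * stats::pnorm(-abs(W - mu) / sqrt(sig2))
}

## one feature, one split: rank-sum p and AUC (= U / (n1 * n2))
rank_sum_test <- function(x, in_cluster, exact_max = 10) {
  idx1 <- which(in_cluster)
  n1 <- length(idx1); n2 <- length(x) - n1
  if (stats::sd(x) < .Machine$double.eps)
    return(c(p = 1, auc = 0.5))
  r <- rank(x)
  U <- sum(r[idx1]) - n1 * (n1 + 1) / 2
  p <- if (n1 <= exact_max && n2 <= exact_max)
    wilcoxon_exact_p(r, idx1) else wilcoxon_normal_p(r, idx1)
  c(p = min(p, 1), auc = U / (n1 * n2))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment (monotone, capped at
#' 1); a thin wrapper over [stats::p.adjust()].
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}

#' One-vs-rest differential features for one cluster
#'
#' For every feature, a two-sided Wilcoxon rank-sum test of the cluster's
#' cells against all other cells (exact enumeration when both groups have
#' at most 10 cells, else a tie-corrected normal approximation), the group
#' means, the difference of group means as `log_fc` (the data are already
#' log-scale for expression, so this is a log fold change) and the AUC (`U / (n1 n2)`, the rank-sum effect size).
#' P-values are BH-adjusted across features within the cluster.
#'
#' @param x a [feature_matrix] (cells x features).
#' @param labels a `cluster_assignment` or integer label vector.
#' @param cluster the cluster tested against the rest; needs at least 3
#'   cells on each side.
#' @param alpha significance threshold applied to the adjusted p (default
#'   0.01).
#' @return a `marker_table` data.frame with one row per feature: `feature`,
#'   `cluster`, `mean_in`, `mean_out`, `log_fc`, `auc`, `wilcoxon_p`,
#'   `adj_p`, `significant`.
#' @export
wilcoxon_de <- function(x, labels, cluster, alpha = 0.01) {
  cl <- if (inherits(labels, "cluster_assignment")) labels$labels else labels
  stopifnot(length(cl) == nrow(x))
  in_cluster <- cl == cluster
  if (sum(in_cluster) < 3 || sum(!in_cluster) < 3)
    stop("cluster and complement each need at least 3 cells")
  xm <- unclass(x)
  res <- t(apply(xm, 2, rank_sum_test, in_cluster = in_cluster))
  mean_in <- colMeans(xm[in_cluster, , drop = FALSE])
  mean_out <- colMeans(xm[!in_cluster, , drop = FALSE])
  tab <- data.frame(feature = colnames(xm), cluster = cluster,
                    mean_in = mean_in, mean_out = mean_out,
                    log_fc = mean_in - mean_out,
                    auc = res[, "auc"], wilcoxon_p = res[, "p"],
                    adj_p = bh_adjust(res[, "p"]),
                    row.names = NULL)
  tab$significant <- tab$adj_p < alpha
  class(tab) <- c("marker_table", "data.frame")
  tab
}

#' Differential features for every cluster
#'
#' Runs [wilcoxon_de()] one-vs-rest for each cluster present in the
#' labelling and stacks the tables. Clusters with fewer than 3 cells (or
#' complement smaller than 3) are skipped with a message.
#'
#' @inheritParams wilcoxon_de
#' @return a `marker_table` with one row per (feature, testable cluster).
#' @export
wilcoxon_de_all <- function(x, labels, alpha = 0.01) {
  cl <- if (inherits(labels, "cluster_assignment")) labels$labels else labels
  ks <- sort(unique(cl))
  testable <- vapply(ks, function(k)
    sum(cl == k) >= 3 && sum(cl != k) >= 3, logical(1))
  if (!all(testable))
    message("skipping clusters with fewer than 3 cells: ",
            paste(ks[!testable], collapse = ", "))
  out <- do.call(rbind, lapply(ks[testable], function(k)
    wilcoxon_de(x, cl, k, alpha)))
  class(out) <- c("marker_table", "data.frame")
  out
}

#' Select marker features from a differential table
#'
#' Markers are features significantly *up* in their cluster: adjusted p
#' strictly below `alpha` and positive log fold change. Optional
#' permissive pre-filters on minimum fold change and detection fraction
#' are off by default.
#'
#' @param table a `marker_table`.
#' @param alpha adjusted-p threshold (strict `<`; default 0.01).
#' @param min_log_fc optional minimum log fold change (default 0,
#'   i.e. any positive shift).
#' @return named list, one character vector of marker features per cluster.
#' @export
select_markers <- function(table, alpha = 0.01, min_log_fc = 0) {
  if (nrow(table) == 0) return(list())
  keep <- table$adj_p < alpha & table$log_fc > min_log_fc
  split(table$feature[keep], paste0("cluster", table$cluster[keep]))
}

#' Representative electrophysiological features per cluster
#'
#' Applies the one-vs-rest Wilcoxon/BH procedure to the *absolute values*
#' of the standardized e-features, so a feature whose magnitude (in either
#' direction) distinguishes a cluster is flagged.
#'
#' @param e standardized electrophysiology [feature_matrix].
#' @param labels cluster labels (`cluster_assignment` or vector).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return a `marker_table` over all clusters, computed on `|e|`.
#' @export
representative_efeatures <- function(e, labels, alpha = 0.05) {
  abs_e <- feature_matrix(abs(unclass(e)), rownames(e), colnames(e),
                          modality_of(e))
  wilcoxon_de_all(abs_e, labels, alpha)
}

#' Write a marker table as TSV
#' @param table a `marker_table`. @param path output path.
#' @return `path`, invisibly.
#' @export
write_marker_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
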