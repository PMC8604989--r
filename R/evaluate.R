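#' Per-cell paired distances on the latent space
#'
#' Euclidean distance between each cell's electrophysiology-view and
#' expression-view coordinates. With `standardize_per_cell = TRUE`
#' (default) every row of the stacked 2n x d coordinate matrix is z-scored
#' across its d entries first, which makes methods with different latent
#' scales comparable.
#'
#' @param emb a `manifold_alignment` (or any list with `e_coords` and
#'   `t_coords` over the same cells).
#' @param standardize_per_cell z-score each coordinate row first; requires
#'   `d >= 2`.
#' @return list of class `alignment_metrics`: `paired_distances` (per
#'   cell), `mean_paired_distance`, `standardized`.
#' @export
paired_distance <- function(emb, standardize_per_cell = TRUE) {
  E <- emb$e_coords; T_ <- emb$t_coords
  stopifnot(nrow(E) == nrow(T_), ncol(E) == ncol(T_))
  if (standardize_per_cell) {
    if (ncol(E) < 2)
      stop("per-cell standardization needs d >= 2 (zero-variance rows)")
    zrow <- function(m) {
      mu <- rowMeans(m)
      sd <- apply(m, 1, stats::sd)
      sd[sd < .Machine$double.eps] <- 1
      (m - mu) / sd
    }
    E <- zrow(E); T_ <- zrow(T_)
  }
  d <- sqrt(rowSums((E - T_)^2))
  structure(list(paired_distances = stats::setNames(d, rownames(emb$e_coords)),
                 mean_paired_distance = mean(d),
                 standardized = standardize_per_cell),
            class = "alignment_metrics")
}

#' Fraction of samples closer than the true match (FOSCTTM)
#'
#' For each cell in one modality, the fraction of the other modality's
#' cells that lie strictly closer (Euclidean, on the latent space) than
#' that cell's true match, divided by n - 1. 0 means perfect alignment,
#' about 0.5 is what a random alignment gives. The score is computed in
#' both directions and averaged; the per-direction means are also
#' reported. Distance ties count as not closer.
#'
#' @param emb a `manifold_alignment` (or compatible list).
#' @return list of class `alignment_metrics`: `foscttm_per_cell` (average
#'   of the two directions per cell), `mean_foscttm`, `mean_by_direction`.
#' @export
foscttm <- function(emb) {
  E <- emb$e_coords; T_ <- emb$t_coords
  n <- nrow(E)
  stopifnot(n >= 2, nrow(T_) == n)
  cross <- outer(rowSums(E^2), rep(1, n)) + outer(rep(1, n), rowSums(T_^2)) -
    2 * E %*% t(T_)
  cross[cross < 0] <- 0                       # numerical guard
  true_d <- diag(cross)
  frac_e <- (rowSums(cross < true_d) - 0) / (n - 1)        # e -> t direction
  frac_t <- (colSums(cross < rep(true_d, each = n)) ) / (n - 1)  # t -> e
  per_cell <- (frac_e + frac_t) / 2
  structure(list(foscttm_per_cell = stats::setNames(per_cell, rownames(E)),
                 mean_foscttm = mean(per_cell),
                 mean_by_direction = c(e_to_t = mean(frac_e),
                                       t_to_e = mean(frac_t))),
            class = "alignment_metrics")
}

#' @export
print.alignment_metrics <- function(x, ...) {
  if (!is.null(x$mean_paired_distance))
    cat(sprintf("mean paired distance%s: %.4f\n",
                if (isTRUE(x$standardized)) " (standardized)" else "",
                x$mean_paired_distance))
  if (!is.null(x$mean_foscttm))
    cat(sprintf("mean FOSCTTM: %.4f\n", x$mean_foscttm))
  invisible(x)
}

#' Silhouette widths by external label
#'
#' Standard Euclidean silhouette of a labelling of latent coordinates,
#' in [-1, 1] per cell; singleton labels get silhouette 0.
#'
#' @param coords n x d coordinate matrix.
#' @param labels vector of length n with at least two distinct values.
#' @return list: `per_cell`, `mean_by_label`, `overall`.
#' @export
silhouette_by_label <- function(coords, labels) {
  labels <- as.factor(labels)
  stopifnot(nrow(coords) == length(labels), nlevels(labels) >= 2)
  sil <- cluster::silhouette(as.integer(labels), stats::dist(coords))
  widths <- sil[, "sil_width"]
  list(per_cell = widths,
       mean_by_label = tapply(widths, labels, mean),
       overall = mean(widths))
}

#' Semi-supervised alignment evaluation
#'
#' Emulates partial supervision: only a random fraction of the true
#' cell-to-cell correspondences is given to the aligner as prior, and the
#' alignment is scored on the held-out cells only.
#'
#' @param ds an [mm_dataset].
#' @param config an [alignment_config] (method `"nma"` or `"lma"`).
#' @param observed_fraction fraction of cells whose correspondence is
#'   observed, in (0, 1).
#' @param seed seed for the observed-cell draw.
#' @return list: `fit` (the `manifold_alignment`), `observed` /`held_out`
#'   (cell indices), `paired` and `foscttm` metrics restricted to the
#'   held-out cells.
#' @export
semi_supervised_eval <- function(ds, config, observed_fraction, seed = 1L) {
  stopifnot(observed_fraction > 0, observed_fraction < 1)
  n <- nrow(ds$e)
  set.seed(seed)
  observed <- sort(sample.int(n, ceiling(observed_fraction * n)))
  held_out <- setdiff(seq_len(n), observed)
  C <- correspondence_from_pairs(n, cbind(observed, observed))
  fit <- manifold_align(ds, correspondence = C, config = config)
  sub <- list(e_coords = fit$e_coords[held_out, , drop = FALSE],
              t_coords = fit$t_coords[held_out, , drop = FALSE])
  list(fit = fit, observed = observed, held_out = held_out,
       paired = paired_distance(sub, standardize_per_cell = ncol(sub$e_coords) > 1),
       foscttm = foscttm(sub))
}
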