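#' Latent-to-latent multivariate regression
#'
#' Ordinary least squares of the electrophysiological latent coordinates
#' on the transcriptomic latent coordinates, in closed form
#' `B = (Xt' Xt)^-1 Xt' Xe` with no intercept (the latent components are
#' near-centred by construction).
#'
#' @param xt_lat n x d predictor matrix (transcriptomic latent space).
#' @param xe_lat n x d response matrix (electrophysiological latent space).
#' @return an object of class `latent_regression`: `B` (d x d), `r2_train`
#'   (in-sample R-squared about the column means), `fitted`.
#' @export
latent_regression <- function(xt_lat, xe_lat) {
  xt_lat <- as.matrix(xt_lat); xe_lat <- as.matrix(xe_lat)
  stopifnot(nrow(xt_lat) == nrow(xe_lat), nrow(xt_lat) > ncol(xt_lat))
  G <- crossprod(xt_lat)
  B <- if (rcond(G) < 1e-12) {
    warning("singular Gram matrix; using pseudoinverse")
    pseudo_solve(G, crossprod(xt_lat, xe_lat))
  } else solve(G, crossprod(xt_lat, xe_lat))
  fitted <- xt_lat %*% B
  resid <- xe_lat - fitted
  tot <- sweep(xe_lat, 2, colMeans(xe_lat))
  structure(list(B = B, fitted = fitted,
                 r2_train = 1 - sum(resid^2) / sum(tot^2)),
            class = "latent_regression")
}

pseudo_solve <- function(A, b) {
  sv <- svd(A)
  pos <- sv$d > max(sv$d) * 1e-12
  sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% b) / sv$d[pos])
}

#' @export
print.latent_regression <- function(x, ...) {
  cat(sprintf("latent_regression: %d -> %d components, train R2 = %.4f\n",
              nrow(x$B), ncol(x$B), x$r2_train))
  invisible(x)
}

#' Cross-validated R-squared of the latent-to-latent regression
#'
#' Repeated k-fold cross-validation: per repetition the cells are randomly
#' partitioned into `folds` subsets; each subset in turn is held out, the
#' coefficient matrix is estimated on the rest, and
#' `R2 = 1 - ||Xe_test - Xt_test B||^2 / ||Xe_test||^2`
#' is computed with both held-out blocks centred by their own (testing-set)
#' column means. The reported value averages over all folds and
#' repetitions.
#'
#' @param xt_lat,xe_lat latent coordinate matrices (n x d).
#' @param folds number of folds (default 10).
#' @param reps number of repetitions (default 20).
#' @param seed seed for the fold draws.
#' @return list: `mean_r2`, `per_fold` (data.frame rep, fold, r2).
#' @export
cv_r2 <- function(xt_lat, xe_lat, folds = 10, reps = 20, seed = 1L) {
  xt_lat <- as.matrix(xt_lat); xe_lat <- as.matrix(xe_lat)
  n <- nrow(xt_lat)
  stopifnot(n >= folds)
  set.seed(seed)
  rows <- vector("list", reps * folds)
  i <- 0
  for (r in seq_len(reps)) {
    fold_of <- sample(rep_len(seq_len(folds), n))
    for (fo in seq_len(folds)) {
      test <- which(fold_of == fo)
      fit <- latent_regression(xt_lat[-test, , drop = FALSE],
                               xe_lat[-test, , drop = FALSE])
      Xt_te <- scale(xt_lat[test, , drop = FALSE], scale = FALSE)
      Xe_te <- scale(xe_lat[test, , drop = FALSE], scale = FALSE)
      resid <- Xe_te - Xt_te %*% fit$B
      i <- i + 1
      rows[[i]] <- data.frame(rep = r, fold = fo,
                              r2 = 1 - sum(resid^2) / sum(Xe_te^2))
    }
  }
  per_fold <- do.call(rbind, rows)
  list(mean_r2 = mean(per_fold$r2), per_fold = per_fold)
}

#' Predict one electrophysiological feature from a gene set
#'
#' Linear regression (with intercept) of a single e-feature on the
#' expression of a gene set -- typically a cluster's differentially
#' expressed genes -- over all cells, with a single random train/test
#' split. Train and test R-squared are computed about the respective
#' split's mean response.
#'
#' @param xt expression [feature_matrix] (or plain matrix) restricted to
#'   the predictor genes.
#' @param y numeric response vector, one e-feature over the same cells.
#' @param train_frac fraction of cells used for training (default 0.9).
#' @param seed seed for the split.
#' @return an object of class `efeature_prediction`: `coefficients`
#'   (intercept first), `r2_train`, `r2_test`, `train_idx`, `predicted`
#'   (held-out predictions), `observed`.
#' @export
predict_efeature_from_degs <- function(xt, y, train_frac = 0.9, seed = 1L) {
  X <- unclass(xt)
  stopifnot(nrow(X) == length(y), ncol(X) >= 1)
  if (stats::sd(y) < .Machine$double.eps)
    stop("zero-variance response")
  n <- nrow(X)
  set.seed(seed)
  train <- sort(sample.int(n, round(train_frac * n)))
  test <- setdiff(seq_len(n), train)
  Xtr <- cbind(1, X[train, , drop = FALSE])
  if (length(train) <= ncol(X))
    warning("fewer training cells than predictors; pseudoinverse fit")
  beta <- pseudo_solve(crossprod(Xtr), crossprod(Xtr, y[train]))
  pred_tr <- drop(Xtr %*% beta)
  pred_te <- drop(cbind(1, X[test, , drop = FALSE]) %*% beta)
  r2 <- function(obs, pred) 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  structure(list(coefficients = drop(beta), r2_train = r2(y[train], pred_tr),
                 r2_test = r2(y[test], pred_te), train_idx = train,
                 predicted = pred_te, observed = y[test],
                 seed = as.integer(seed)),
            class = "efeature_prediction")
}

#' @export
print.efeature_prediction <- function(x, ...) {
  cat(sprintf("efeature_prediction: %d predictors, train R2 = %.3f, test R2 = %.3f\n",
              length(x$coefficients) - 1, x$r2_train, x$r2_test))
  invisible(x)
}

#' Feature-latent correlations for bibiplots
#'
#' Pearson correlation of every original feature with the first
#' `n_components` latent components of its own modality. For each biplot
#' plane (pair of components) the display radius is
#' `sqrt(r_a^2 + r_b^2)`; features with radius strictly above
#' `radius_threshold` in a plane are flagged for display.
#'
#' @param m a [feature_matrix] of one modality.
#' @param emb a `manifold_alignment` over the same cells.
#' @param n_components number of latent components (default 3).
#' @param radius_threshold display threshold on the plane radius
#'   (default 0.6, strict `>`).
#' @return list: `correlations` (features x components), `planes`
#'   (data.frame feature, comp_a, comp_b, radius, display).
#' @export
feature_latent_correlations <- function(m, emb, n_components = 3,
                                        radius_threshold = 0.6) {
  coords <- if (identical(modality_of(m), "electrophysiology"))
    emb$e_coords else emb$t_coords
  stopifnot(nrow(m) == nrow(coords), n_components <= ncol(coords))
  L <- coords[, seq_len(n_components), drop = FALSE]
  x <- unclass(m)
  const <- apply(x, 2, stats::sd) < .Machine$double.eps
  r <- matrix(0, ncol(x), n_components,
              dimnames = list(colnames(x), colnames(L)))
  if (any(!const))
    r[!const, ] <- stats::cor(x[, !const, drop = FALSE], L)
  pairs <- utils::combn(n_components, 2)
  planes <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    data.frame(feature = rownames(r), comp_a = a, comp_b = b,
               radius = sqrt(r[, a]^2 + r[, b]^2), row.names = NULL)
  }))
  planes$display <- planes$radius > radius_threshold
  list(correlations = r, planes = planes)
}
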