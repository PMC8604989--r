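#' Alignment configuration
#'
#' @param k intra-modal kNN neighbours (default 2).
#' @param d latent dimension (default 3).
#' @param mu trade-off between intra-modal manifold preservation and
#'   cross-modal correspondence, in `[0, 1]` (default 0.5, equal weight).
#' @param method one of `"nma"`, `"lma"`, `"cca"`, `"rrr"`, `"pca"`.
#' @param eig_tol eigenvalues at or below this are treated as trivial
#'   (constant-on-a-component) solutions and discarded (default 1e-8).
#' @param seed integer seed for any randomized fallback (unused by the
#'   deterministic dense solver; kept for interface stability).
#' @return an `alignment_config` list.
#' @export
alignment_config <- function(k = 2, d = 3, mu = 0.5,
                             method = c("nma", "lma", "cca", "rrr", "pca"),
                             eig_tol = 1e-8, seed = 1L) {
  method <- match.arg(method)
  stopifnot(d >= 1, mu >= 0, mu <= 1, k >= 1, eig_tol > 0)
  structure(list(k = k, d = d, mu = mu, method = method, eig_tol = eig_tol,
                 seed = as.integer(seed)),
            class = "alignment_config")
}

## fix eigenvector column signs: largest-magnitude entry positive
fix_signs <- function(v) {
  s <- apply(v, 2, function(col) sign(col[which.max(abs(col))]))
  s[s == 0] <- 1
  sweep(v, 2, s, "*")
}

## generalized eigenproblem L v = lambda D v with diagonal D (vector deg).
## Returns eigenpairs sorted by ascending eigenvalue, D-orthonormal vectors.
geigen_diag <- function(L, deg, eig_tol) {
  if (any(deg <= 0))
    stop(sum(deg <= 0), " isolated node(s): zero degree in the joint graph")
  s <- 1 / sqrt(deg)
  M <- L * tcrossprod(s)            # D^{-1/2} L D^{-1/2}
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  ord <- rev(seq_along(e$values))   # ascending
  list(values = e$values[ord], vectors = s * e$vectors[, ord, drop = FALSE])
}

## generalized eigenproblem A u = lambda B u for symmetric A, B >= 0.
## A rank-deficient B is handled by restricting the pencil to B's numerical
## column space (reported via message): directions with B u ~ 0 are 0/0
## artefacts of collinear features, not admissible embeddings.
geigen_pair <- function(A, B, eig_tol) {
  A <- (A + t(A)) / 2
  B <- (B + t(B)) / 2
  eB <- eigen(B, symmetric = TRUE)
  keep <- eB$values > max(eB$values) * 1e-10
  ridge_used <- !all(keep)
  if (ridge_used)
    message("rank-deficient constraint matrix: restricted to its column space")
  V <- eB$vectors[, keep, drop = FALSE]
  W <- V %*% diag(1 / sqrt(eB$values[keep]), sum(keep))  # B^{-1/2} on range
  M <- crossprod(W, A %*% W)
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  ord <- rev(seq_along(e$values))
  list(values = e$values[ord],
       vectors = W %*% e$vectors[, ord, drop = FALSE],
       ridge_used = ridge_used)
}

#' Graph-embedding loss of a joint embedding
#'
#' The quadratic form `tr(Q' L Q)` of the joint graph, equal to half the
#' sum over ordered node pairs of `w_ij * ||q_i - q_j||^2`. This is the
#' alignment objective: the cross-modal term pulls corresponding cells
#' together with weight `1 - mu` while the intra-modal terms preserve each
#' view's kNN manifold with weight `mu` (cross pairs counted in both
#' orders, as in the symmetric joint-matrix form).
#'
#' @param jg a `joint_graph` from [build_joint()].
#' @param Q 2n x d stacked embedding (electrophysiology rows first).
#' @return the scalar loss.
#' @export
joint_loss <- function(jg, Q) sum(Q * (jg$laplacian %*% Q))

#' Align two single-cell modalities on a shared latent space
#'
#' The central fitting function. Given paired electrophysiology and
#' expression matrices over the same cells it co-embeds both views in d
#' dimensions by one of:
#'
#' * `"nma"` -- nonlinear (nonparametric) manifold alignment: build binary
#'   kNN graphs per view, assemble the joint graph with the cross-modal
#'   correspondence, and take the bottom non-trivial eigenvectors of the
#'   generalized problem `L v = lambda D v` under the non-degeneracy
#'   constraint `Q' D Q = I`. Outputs cell coordinates directly.
#' * `"lma"` -- linear manifold alignment: the same objective restricted to
#'   linear maps, solved in feature space; returns projection matrices.
#' * `"cca"` -- canonical correlation analysis (whitened cross-covariance
#'   SVD, ridge 1e-6), unit-variance canonical variates.
#' * `"rrr"` -- reduced-rank regression of the e-view on the t-view (OLS
#'   followed by rank-d truncation of the fitted values).
#' * `"pca"` -- per-modality PCA with no alignment (negative control).
#'
#' Embeddings are defined up to per-column sign and rotation within
#' degenerate eigenspaces; a deterministic sign convention (largest-
#' magnitude entry positive) is applied so repeated runs agree exactly.
#'
#' @param ds an [mm_dataset]; features should already be standardized
#'   (see [standardize_features()]).
#' @param method alignment method, see above.
#' @param correspondence cross-modal prior, an n x n 0/1 matrix from
#'   [correspondence_from_pairs()]; default full identity (used by
#'   `"nma"`/`"lma"` only).
#' @param k,d,mu,eig_tol,seed see [alignment_config()].
#' @param config an [alignment_config] overriding the individual arguments.
#' @return an object of class `manifold_alignment` with components
#'   `e_coords`, `t_coords` (n x d matrices), `cell_ids`, `method`,
#'   `eigenvalues` (retained generalized eigenvalues, nma/lma),
#'   `loss` (graph-embedding loss, nma/lma), `projections` (parametric
#'   methods), `details` (method-specific diagnostics) and `config`.
#' @examples
#' ds <- simulate_patchseq(synth_config(n_cells = 120, d2 = 40, seed = 7))
#' ds <- mm_dataset(standardize_features(ds$e), standardize_features(ds$t),
#'                  ds$labels)
#' fit <- manifold_align(ds, "nma")
#' fit
#' @export
manifold_align <- function(ds, method = c("nma", "lma", "cca", "rrr", "pca"),
                           correspondence = NULL, k = 2, d = 3, mu = 0.5,
                           eig_tol = 1e-8, seed = 1L, config = NULL) {
  stopifnot(inherits(ds, "mm_dataset"))
  if (is.null(config)) {
    method <- match.arg(method)
    config <- alignment_config(k, d, mu, method, eig_tol, seed)
  }
  method <- config$method
  n <- nrow(ds$e)
  if (anyNA(ds$e) || anyNA(ds$t))
    stop("dataset has missing values; run filter_complete first")
  fit <- switch(method,
                nma = align_nma(ds, correspondence, config),
                lma = align_lma(ds, correspondence, config),
                cca = align_cca(ds, config$d),
                rrr = align_rrr(ds, config$d),
                pca = align_pca(ds, config$d))
  fit$cell_ids <- rownames(ds$e)
  rownames(fit$e_coords) <- rownames(fit$t_coords) <- fit$cell_ids
  colnames(fit$e_coords) <- colnames(fit$t_coords) <-
    paste0("dim", seq_len(ncol(fit$e_coords)))
  fit$method <- method
  fit$config <- config
  class(fit) <- "manifold_alignment"
  fit
}

align_nma <- function(ds, C, cfg) {
  n <- nrow(ds$e)
  if (is.null(C)) C <- identity_correspondence(n)
  W_e <- knn_graph(ds$e, cfg$k)
  W_t <- knn_graph(ds$t, cfg$k)
  jg <- build_joint(W_e, W_t, unclass(C), cfg$mu)
  eig <- geigen_diag(jg$laplacian, jg$degree, cfg$eig_tol)
  keep <- which(eig$values > cfg$eig_tol)
  n_trivial <- length(eig$values) - length(keep)
  if (length(keep) < cfg$d)
    stop("only ", length(keep), " non-trivial eigenpairs available, need ",
         cfg$d)
  sel <- keep[seq_len(cfg$d)]
  Q <- fix_signs(eig$vectors[, sel, drop = FALSE])
  list(e_coords = Q[seq_len(n), , drop = FALSE],
       t_coords = Q[n + seq_len(n), , drop = FALSE],
       eigenvalues = eig$values[sel],
       loss = joint_loss(jg, Q),
       projections = NULL,
       details = list(n_trivial = n_trivial,
                      isolated = jg$isolated,
                      connected = n_trivial == 1))
}

align_lma <- function(ds, C, cfg) {
  n <- nrow(ds$e)
  if (is.null(C)) C <- identity_correspondence(n)
  Xe <- unclass(ds$e); Xt <- unclass(ds$t)
  d1 <- ncol(Xe); d2 <- ncol(Xt)
  W_e <- knn_graph(ds$e, cfg$k)
  W_t <- knn_graph(ds$t, cfg$k)
  jg <- build_joint(W_e, W_t, unclass(C), cfg$mu)
  Z <- matrix(0, 2 * n, d1 + d2)
  Z[seq_len(n), seq_len(d1)] <- Xe
  Z[n + seq_len(n), d1 + seq_len(d2)] <- Xt
  A <- crossprod(Z, jg$laplacian %*% Z)
  B <- crossprod(Z, jg$degree * Z)
  eig <- geigen_pair(A, B, cfg$eig_tol)
  keep <- which(eig$values > cfg$eig_tol)
  if (length(keep) < cfg$d)
    stop("only ", length(keep), " non-trivial eigenpairs available, need ",
         cfg$d)
  sel <- keep[seq_len(cfg$d)]
  U <- fix_signs(eig$vectors[, sel, drop = FALSE])
  f <- U[seq_len(d1), , drop = FALSE]
  g <- U[d1 + seq_len(d2), , drop = FALSE]
  rownames(f) <- colnames(Xe); rownames(g) <- colnames(Xt)
  Q <- Z %*% U
  list(e_coords = Xe %*% f, t_coords = Xt %*% g,
       eigenvalues = eig$values[sel],
       loss = joint_loss(jg, Q),
       projections = list(f = f, g = g),
       details = list(ridge_used = eig$ridge_used, isolated = jg$isolated))
}

## symmetric inverse square root with ridge
inv_sqrt <- function(S, ridge = 1e-6) {
  S <- (S + t(S)) / 2
  diag(S) <- diag(S) + ridge
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, max(e$values) * 1e-12)
  e$vectors %*% (t(e$vectors) / sqrt(vals))
}

align_cca <- function(ds, d, ridge = 1e-6) {
  Xe <- unclass(ds$e); Xt <- unclass(ds$t)
  if (d > min(ncol(Xe), ncol(Xt)))
    stop("d exceeds the smaller view dimension")
  ce <- colMeans(Xe); ct <- colMeans(Xt)
  Xec <- sweep(Xe, 2, ce); Xtc <- sweep(Xt, 2, ct)
  n <- nrow(Xec)
  See <- crossprod(Xec) / (n - 1)
  Stt <- crossprod(Xtc) / (n - 1)
  Set <- crossprod(Xec, Xtc) / (n - 1)
  Wei <- inv_sqrt(See, ridge)
  Wti <- inv_sqrt(Stt, ridge)
  sv <- svd(Wei %*% Set %*% Wti, nu = d, nv = d)
  a <- Wei %*% sv$u                     # canonical directions, e side
  b <- Wti %*% sv$v
  a <- fix_signs(a); b <- fix_signs(b)
  ## re-sync signs so that paired variates stay positively correlated
  for (j in seq_len(d)) {
    if (stats::cor(Xec %*% a[, j], Xtc %*% b[, j]) < 0) b[, j] <- -b[, j]
  }
  rownames(a) <- colnames(Xe); rownames(b) <- colnames(Xt)
  list(e_coords = Xec %*% a, t_coords = Xtc %*% b,
       eigenvalues = NULL, loss = NULL,
       projections = list(f = a, g = b, center_e = ce, center_t = ct),
       details = list(canonical_cors = pmin(sv$d[seq_len(d)], 1)))
}

align_rrr <- function(ds, d, ridge = 1e-6) {
  Xe <- unclass(ds$e); Xt <- unclass(ds$t)
  if (d > min(ncol(Xe), ncol(Xt)))
    stop("d exceeds the smaller view dimension")
  ce <- colMeans(Xe); ct <- colMeans(Xt)
  Y <- sweep(Xe, 2, ce); X <- sweep(Xt, 2, ct)
  G <- crossprod(X)
  ridge_used <- FALSE
  if (rcond(G) < 1e-12) {
    ridge_used <- TRUE
    message("collinear predictors: ridge regularization applied")
    diag(G) <- diag(G) + ridge * mean(diag(G))
  }
  B <- solve(G, crossprod(X, Y))
  fitted <- X %*% B
  sv <- svd(fitted, nu = d, nv = d)
  V <- fix_signs(sv$v)
  rownames(V) <- colnames(Xe)
  list(e_coords = Y %*% V, t_coords = fitted %*% V,
       eigenvalues = NULL, loss = NULL,
       projections = list(B = B, V = V, center_e = ce, center_t = ct),
       details = list(ridge_used = ridge_used,
                      singular_values = sv$d[seq_len(d)]))
}

align_pca <- function(ds, d) {
  pe <- pca_embed(ds$e, d)
  pt <- pca_embed(ds$t, d)
  list(e_coords = pe$scores, t_coords = pt$scores,
       eigenvalues = NULL, loss = NULL,
       projections = list(f = pe$rotation, g = pt$rotation,
                          center_e = pe$center, center_t = pt$center),
       details = list(var_explained_e = pe$var_explained,
                      var_explained_t = pt$var_explained))
}

#' Per-modality PCA embedding
#'
#' Centred PCA of one view; the no-alignment control.
#'
#' @param m a [feature_matrix].
#' @param d number of components.
#' @return list with `scores` (n x d), `rotation`, `center`,
#'   `var_explained` (fraction per component, non-increasing).
#' @export
pca_embed <- function(m, d) {
  x <- unclass(m)
  if (d > ncol(x)) stop("d exceeds the number of features")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rot <- fix_signs(p$rotation[, seq_len(d), drop = FALSE])
  scores <- sweep(x, 2, p$center) %*% rot
  list(scores = scores, rotation = rot, center = p$center,
       var_explained = (p$sdev^2 / sum(p$sdev^2))[seq_len(d)])
}

#' @export
print.manifold_alignment <- function(x, ...) {
  cat(sprintf("manifold_alignment (%s): %d cells embedded in %d dimensions\n",
              toupper(x$method), nrow(x$e_coords), ncol(x$e_coords)))
  if (!is.null(x$loss))
    cat(sprintf("  graph-embedding loss: %.6g\n", x$loss))
  if (!is.null(x$details$canonical_cors))
    cat("  canonical correlations:",
        paste(sprintf("%.3f", x$details$canonical_cors), collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
summary.manifold_alignment <- function(object, ...) {
  pd <- paired_distance(object,
                        standardize_per_cell = ncol(object$e_coords) > 1)
  fs <- foscttm(object)
  out <- list(method = object$method, n = nrow(object$e_coords),
              d = ncol(object$e_coords),
              mean_paired_distance = pd$mean_paired_distance,
              mean_foscttm = fs$mean_foscttm,
              eigenvalues = object$eigenvalues, loss = object$loss)
  class(out) <- "summary.manifold_alignment"
  out
}

#' @export
print.summary.manifold_alignment <- function(x, ...) {
  cat(sprintf("%s alignment of %d cells (d = %d)\n", toupper(x$method), x$n,
              x$d))
  cat(sprintf("  mean paired distance (standardized): %.4f\n",
              x$mean_paired_distance))
  cat(sprintf("  mean FOSCTTM: %.4f\n", x$mean_foscttm))
  if (!is.null(x$loss)) cat(sprintf("  embedding loss: %.6g\n", x$loss))
  invisible(x)
}

#' @export
coef.manifold_alignment <- function(object, ...) {
  if (is.null(object$projections))
    stop("nonparametric alignment has no projection matrices")
  object$projections
}

#' Project new cells with a parametric alignment
#'
#' Applies the stored linear maps to held-out cells. Only parametric
#' methods (`lma`, `cca`, `rrr`, `pca`) support this; nonlinear manifold
#' alignment is nonparametric and has no out-of-sample map.
#'
#' @param object a fitted `manifold_alignment`.
#' @param newdata an [mm_dataset] (or list with elements `e` and/or `t`)
#'   with the same features as the training data.
#' @param ... unused.
#' @return list with `e_coords` and/or `t_coords` for the new cells.
#' @export
predict.manifold_alignment <- function(object, newdata, ...) {
  if (is.null(object$projections))
    stop("nonparametric alignment (nma) cannot project new cells")
  pr <- object$projections
  out <- list()
  if (!is.null(newdata$e)) {
    Xe <- unclass(newdata$e)
    out$e_coords <- switch(object$method,
      lma = Xe %*% pr$f,
      cca = ,
      pca = sweep(Xe, 2, pr$center_e) %*% pr$f,
      rrr = sweep(Xe, 2, pr$center_e) %*% pr$V)
  }
  if (!is.null(newdata$t)) {
    Xt <- unclass(newdata$t)
    out$t_coords <- switch(object$method,
      lma = Xt %*% pr$g,
      cca = ,
      pca = sweep(Xt, 2, pr$center_t) %*% pr$g,
      rrr = (sweep(Xt, 2, pr$center_t) %*% pr$B) %*% pr$V)
  }
  out
}

#' @export
plot.manifold_alignment <- function(x, dims = c(1, 2), labels = NULL, ...) {
  stopifnot(length(dims) == 2)
  E <- x$e_coords[, dims, drop = FALSE]
  T_ <- x$t_coords[, dims, drop = FALSE]
  col_e <- grDevices::adjustcolor("firebrick", 0.6)
  col_t <- grDevices::adjustcolor("steelblue", 0.6)
  graphics::plot(rbind(E, T_), type = "n",
                 xlab = paste0("dim", dims[1]), ylab = paste0("dim", dims[2]),
                 main = sprintf("%s co-embedding", toupper(x$method)), ...)
  graphics::segments(E[, 1], E[, 2], T_[, 1], T_[, 2],
                     col = grDevices::adjustcolor("grey", 0.3))
  graphics::points(E, pch = 16, col = col_e, cex = 0.6)
  graphics::points(T_, pch = 17, col = col_t, cex = 0.6)
  graphics::legend("topright", legend = c("electrophysiology", "expression"),
                   pch = c(16, 17), col = c(col_e, col_t), bty = "n")
  invisible(x)
}

#' Write an embedding to CSV with a JSON sidecar
#'
#' Long format: `cell_id`, `modality` (e or t), `dim1..dimd`. Retained
#' eigenvalues and the configuration go to `<path>.json`.
#'
#' @param fit a `manifold_alignment`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(fit, path) {
  df <- data.frame(cell_id = rep(fit$cell_ids, 2),
                   modality = rep(c("e", "t"), each = length(fit$cell_ids)))
  df <- cbind(df, rbind(fit$e_coords, fit$t_coords))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(method = fit$method,
                            eigenvalues = fit$eigenvalues,
                            loss = fit$loss,
                            config = unclass(fit$config)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
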