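#' Concatenate the two latent views into one feature set per cell
#'
#' Cross-modal clustering operates on `[X_e_latent, X_t_latent]`, the
#' horizontal concatenation of both modalities' latent coordinates, so a
#' cluster must be supported by both views.
#'
#' @param emb a `manifold_alignment`.
#' @return a [feature_matrix] (modality `"latent"`) with columns
#'   `dim_e1..dim_ed, dim_t1..dim_td`.
#' @export
combined_features <- function(emb) {
  d <- ncol(emb$e_coords)
  m <- cbind(emb$e_coords, emb$t_coords)
  colnames(m) <- c(paste0("dim_e", seq_len(d)), paste0("dim_t", seq_len(d)))
  feature_matrix(m, rownames(emb$e_coords), colnames(m), "latent")
}

## log multivariate normal density for all rows of x at one component
log_dmvnorm <- function(x, mean, sigma) {
  p <- ncol(x)
  ch <- chol(sigma)
  z <- forwardsolve(t(ch), t(x) - mean)
  -0.5 * p * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

## k-means++ style seeding: spread initial centres, then hard-assign
kmeanspp_init <- function(x, K) {
  n <- nrow(x)
  centers <- matrix(NA_real_, K, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (k in seq_len(K)[-1]) {
    prob <- d2 / sum(d2)
    if (any(!is.finite(prob)) || sum(d2) == 0) prob <- rep(1 / n, n)
    centers[k, ] <- x[sample.int(n, 1, prob = prob), ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[k, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centers
}

#' Fit a Gaussian mixture model by EM
#'
#' Full-covariance GMM fitted by expectation-maximization with k-means++
#' seeded initialization, covariance regularization `reg * mean feature
#' variance` added to each covariance diagonal (so the floor is scale
#' free; latent coordinates can be numerically tiny) and at most `n_iter`
#' iterations (relative log-likelihood tolerance 1e-8). The log-likelihood
#' is checked to be non-decreasing across iterations up to that tolerance.
#' A component that empties is reinitialized once; if it empties again the
#' fit aborts.
#'
#' @param f feature matrix (n cells x p features), `n > K`.
#' @param K number of mixture components.
#' @param seed integer seed for the initialization.
#' @param n_iter maximum EM iterations (default 100).
#' @param reg covariance regularization, as a fraction of the average
#'   feature variance, added to each covariance diagonal (default 1e-6).
#' @return an object of class `gmm_fit`: `K`, `weights`, `means` (K x p),
#'   `covariances` (list of p x p), `log_likelihood`, `loglik_trace`,
#'   `n_iter`, `seed`.
#' @export
fit_gmm <- function(f, K, seed = 1L, n_iter = 100, reg = 1e-6) {
  x <- unclass(f)
  n <- nrow(x); p <- ncol(x)
  stopifnot(n > K, K >= 1, p >= 1)
  reg <- reg * mean(apply(x, 2, stats::var))
  if (reg == 0) reg <- .Machine$double.eps
  set.seed(seed)
  for (attempt in 1:2) {
    centers <- kmeanspp_init(x, K)
    d2 <- vapply(seq_len(K), function(k)
      rowSums((x - matrix(centers[k, ], n, p, byrow = TRUE))^2), numeric(n))
    assign0 <- max.col(-d2, ties.method = "first")
    R <- matrix(0, n, K); R[cbind(seq_len(n), assign0)] <- 1
    w <- colMeans(R)
    mu <- matrix(0, K, p)
    Sig <- vector("list", K)
    loglik <- -Inf
    trace <- numeric(0)
    ok <- TRUE
    for (it in seq_len(n_iter)) {
      ## M step from responsibilities R
      nk <- colSums(R)
      if (any(nk < .Machine$double.eps)) { ok <- FALSE; break }
      w <- nk / n
      for (k in seq_len(K)) {
        mu[k, ] <- colSums(R[, k] * x) / nk[k]
        xc <- sweep(x, 2, mu[k, ])
        S <- crossprod(xc * sqrt(R[, k])) / nk[k]
        diag(S) <- diag(S) + reg
        Sig[[k]] <- (S + t(S)) / 2
      }
      ## E step
      logd <- vapply(seq_len(K), function(k)
        log(w[k]) + log_dmvnorm(x, mu[k, ], Sig[[k]]), numeric(n))
      m <- apply(logd, 1, max)
      lse <- m + log(rowSums(exp(logd - m)))
      new_loglik <- sum(lse)
      if (new_loglik < loglik - 1e-8 * (1 + abs(loglik)))
        stop("EM log-likelihood decreased; numerical failure")
      R <- exp(logd - lse)
      trace <- c(trace, new_loglik)
      if (is.finite(loglik) &&
          abs(new_loglik - loglik) <= 1e-8 * (1 + abs(loglik))) {
        loglik <- new_loglik
        break
      }
      loglik <- new_loglik
    }
    if (ok) break
    if (attempt == 2) stop("a mixture component emptied twice; reduce K")
  }
  structure(list(K = K, weights = w, means = mu, covariances = Sig,
                 log_likelihood = loglik, loglik_trace = trace,
                 n_iter = length(trace), seed = as.integer(seed)),
            class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("gmm_fit: K = %d, log-likelihood %.4f after %d EM iterations\n",
              x$K, x$log_likelihood, x$n_iter))
  cat("  weights:", paste(sprintf("%.3f", x$weights), collapse = ", "), "\n")
  invisible(x)
}

#' Number of free GMM parameters
#' @param K components, @param p feature dimension
#' @noRd
gmm_n_params <- function(K, p) (K - 1) + K * p + K * p * (p + 1) / 2

#' Select the number of mixture components by BIC
#'
#' Fits each candidate K with `restarts` seeded EM restarts (best
#' log-likelihood kept) and computes `BIC = p_free * ln(n) - 2 * lnL`.
#'
#' Two selection rules are provided. The default, `"elbow"`, picks the
#' smallest K after which the BIC gradient becomes insignificant — the
#' first K (in ascending order) whose next BIC improvement is less than
#' `elbow_frac` of the total BIC range over `K_range` (falling back to the
#' BIC minimum when every step is significant). Mixture components are a
#' parametric crutch for clusters that need not be Gaussian; past the true
#' cluster number, extra components keep paying for cluster *shape*
#' (curved or heavy-tailed clusters) with small but steady BIC gains, so
#' the flattening point, not the minimum, tracks the cluster number.
#' `"argmin"` takes the BIC minimum.
#'
#' @param f feature matrix.
#' @param K_range candidate component counts (all `< n`).
#' @param seed base seed; restart r of candidate K uses
#'   `seed + 1000 * K + r`.
#' @param restarts EM restarts per K (default 5).
#' @param n_iter maximum EM iterations per fit.
#' @param rule `"elbow"` (default) or `"argmin"`, see Details.
#' @param elbow_frac significance threshold for a BIC step, as a fraction
#'   of the total BIC range (default 0.05).
#' @return list: `K` (selected), `K_argmin`, `bic_table` (data.frame K,
#'   loglik, bic, d_bic), `fits` (best `gmm_fit` per K).
#' @export
select_K_bic <- function(f, K_range, seed = 1L, restarts = 5, n_iter = 100,
                         rule = c("elbow", "argmin"), elbow_frac = 0.05) {
  rule <- match.arg(rule)
  stopifnot(length(K_range) >= 1, all(K_range < nrow(f)))
  x <- unclass(f)
  n <- nrow(x); p <- ncol(x)
  fits <- vector("list", length(K_range))
  tab <- data.frame(K = K_range, loglik = NA_real_, bic = NA_real_)
  for (i in seq_along(K_range)) {
    K <- K_range[i]
    best <- NULL
    for (r in seq_len(restarts)) {
      fit <- tryCatch(fit_gmm(f, K, seed = seed + 1000L * K + r,
                              n_iter = n_iter),
                      error = function(e) NULL)
      if (!is.null(fit) &&
          (is.null(best) || fit$log_likelihood > best$log_likelihood))
        best <- fit
    }
    if (is.null(best)) stop("no successful EM fit for K = ", K)
    fits[[i]] <- best
    tab$loglik[i] <- best$log_likelihood
    tab$bic[i] <- gmm_n_params(K, p) * log(n) - 2 * best$log_likelihood
  }
  tab$d_bic <- c(NA, diff(tab$bic))
  K_argmin <- tab$K[which.min(tab$bic)]
  K_sel <- K_argmin
  if (rule == "elbow" && nrow(tab) > 1) {
    rng <- diff(range(tab$bic))
    if (rng > 0) {
      flat <- which(tab$d_bic[-1] > -elbow_frac * rng)  # step K -> K+1 small
      if (length(flat)) K_sel <- tab$K[min(flat)]
    } else K_sel <- tab$K[1]
  }
  list(K = K_sel, K_argmin = K_argmin, bic_table = tab, fits = fits)
}

#' Posterior cluster assignment
#'
#' Posterior probability of each component for each cell, computed in log
#' space, with the label taken as the maximum-posterior component (ties to
#' the lower component index).
#'
#' @param model a `gmm_fit`.
#' @param f feature matrix with the model's dimensionality.
#' @return list of class `cluster_assignment`: `labels` (integers 1..K),
#'   `posteriors` (n x K, rows sum to 1).
#' @export
assign_clusters <- function(model, f) {
  x <- unclass(f)
  stopifnot(ncol(x) == ncol(model$means))
  logd <- vapply(seq_len(model$K), function(k)
    log(model$weights[k]) + log_dmvnorm(x, model$means[k, ],
                                        model$covariances[[k]]),
    numeric(nrow(x)))
  logd <- matrix(logd, nrow = nrow(x))
  m <- apply(logd, 1, max)
  post <- exp(logd - (m + log(rowSums(exp(logd - m)))))
  labels <- max.col(post, ties.method = "first")
  structure(list(labels = stats::setNames(labels, rownames(x)),
                 posteriors = post),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("cluster_assignment:", length(x$labels), "cells in",
      length(unique(x$labels)), "clusters\n")
  print(table(x$labels))
  invisible(x)
}

#' Alternative clusterings of the latent space
#'
#' PAM k-medoids (Euclidean) or agglomerative average-linkage hierarchical
#' clustering cut at K clusters, as robustness checks on the GMM clusters.
#' Posteriors are one-hot.
#'
#' @param f feature matrix.
#' @param K number of clusters, `K < n` (K = n returns singletons).
#' @param method `"kmedoid"` or `"hierarchical"`.
#' @param seed accepted for interface symmetry; both methods are
#'   deterministic.
#' @return a `cluster_assignment`.
#' @export
alternative_clusterings <- function(f, K,
                                    method = c("kmedoid", "hierarchical"),
                                    seed = 1L) {
  method <- match.arg(method)
  x <- unclass(f)
  stopifnot(K <= nrow(x))
  set.seed(seed)
  labels <- if (method == "kmedoid") {
    if (K == nrow(x)) seq_len(nrow(x)) else
      cluster::pam(x, K, metric = "euclidean", cluster.only = TRUE)
  } else {
    stats::cutree(stats::hclust(stats::dist(x), method = "average"), k = K)
  }
  post <- matrix(0, nrow(x), K)
  post[cbind(seq_len(nrow(x)), labels)] <- 1
  structure(list(labels = stats::setNames(as.integer(labels), rownames(x)),
                 posteriors = post),
            class = "cluster_assignment")
}

#' Concordance between a clustering and external labels
#'
#' @param assign a `cluster_assignment` (or integer vector of labels).
#' @param labels external per-cell labels (e.g. transcriptomic types).
#' @return list: `contingency` (labels x clusters), `max_fraction` (per
#'   external label, the fraction captured by its best single cluster),
#'   `ari` (adjusted Rand index).
#' @export
cluster_label_concordance <- function(assign, labels) {
  cl <- if (inherits(assign, "cluster_assignment")) assign$labels else assign
  stopifnot(length(cl) == length(labels))
  tab <- table(label = labels, cluster = cl)
  list(contingency = tab,
       max_fraction = apply(tab, 1, max) / rowSums(tab),
       ari = mclust::adjustedRandIndex(cl, labels))
}
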