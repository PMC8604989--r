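#' Binary k-nearest-neighbour similarity graph
#'
#' Euclidean kNN with self excluded; distance ties are broken by the lower
#' cell index so the graph is deterministic. The directed kNN relation is
#' symmetrized by union: an (undirected) edge is present when either cell
#' lists the other among its k nearest. Entries are 0/1 with a zero
#' diagonal.
#'
#' @param m a [feature_matrix] (or plain matrix) with no missing values.
#' @param k number of neighbours, `1 <= k < n`.
#' @param metric only `"euclidean"`.
#' @param weighted if `TRUE`, edges carry heat-kernel weights
#'   `exp(-d^2 / sigma^2)` (sigma = median kNN distance) instead of 1;
#'   off by default.
#' @return symmetric n x n adjacency matrix with the cell ids as dimnames.
#' @export
knn_graph <- function(m, k, metric = "euclidean", weighted = FALSE) {
  metric <- match.arg(metric, "euclidean")
  x <- unclass(m)
  n <- nrow(x)
  if (k >= n) stop("k must be smaller than the number of cells")
  if (k < 1) stop("k must be at least 1")
  if (anyNA(x)) stop("missing values in the feature matrix")
  d <- as.matrix(stats::dist(x))
  adj <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n)) {
    cand <- setdiff(seq_len(n), i)
    ord <- cand[order(d[i, cand], cand)][seq_len(k)]   # lower-index ties
    adj[i, ord] <- 1
  }
  adj <- pmax(adj, t(adj))                              # union symmetrization
  if (weighted) {
    nz <- adj > 0
    sigma <- stats::median(d[nz])
    adj[nz] <- exp(-(d[nz]^2) / sigma^2)
    adj <- (adj + t(adj)) / 2
  }
  diag(adj) <- 0
  adj
}

#' Cross-modal correspondence matrix
#'
#' Entry (i, j) is 1 when cell i of the electrophysiology view is known to
#' be the same cell as cell j of the expression view. Full supervision is
#' the identity; a semi-supervised prior keeps only a subset of the pairs.
#'
#' @param n number of cells per view.
#' @param observed_pairs two-column matrix (or list of length-2 vectors) of
#'   (i, j) indices; duplicates in a row or column are an error.
#' @return an n x n 0/1 matrix of class `correspondence` with attribute
#'   `mask_fraction` (observed rows / n).
#' @export
correspondence_from_pairs <- function(n, observed_pairs) {
  if (is.list(observed_pairs))
    observed_pairs <- do.call(rbind, lapply(observed_pairs, as.integer))
  observed_pairs <- matrix(as.integer(observed_pairs), ncol = 2)
  C <- matrix(0, n, n)
  if (nrow(observed_pairs) > 0) {
    if (any(observed_pairs < 1) || any(observed_pairs > n))
      stop("pair indices out of range")
    if (anyDuplicated(observed_pairs[, 1]) || anyDuplicated(observed_pairs[, 2]))
      stop("duplicate row or column index in correspondence pairs")
    C[observed_pairs] <- 1
  }
  structure(C, mask_fraction = nrow(observed_pairs) / n,
            class = c("correspondence", "matrix", "array"))
}

#' Identity correspondence over n cells
#' @param n number of cells.
#' @return a full-supervision `correspondence` (identity matrix).
#' @export
identity_correspondence <- function(n)
  correspondence_from_pairs(n, cbind(seq_len(n), seq_len(n)))

#' Assemble the joint cross-modal graph
#'
#' Stacks the two intra-modal graphs and the correspondence into the
#' 2n x 2n weight matrix
#' `[[mu * W_e, (1 - mu) * C], [(1 - mu) * C', mu * W_t]]`,
#' with its degree matrix and (unnormalized) graph Laplacian
#' `L = D - W`. `mu` trades off intra-modal manifold preservation against
#' the cross-modal correspondence pull.
#'
#' @param W_e,W_t symmetric intra-modal adjacency matrices over the same
#'   cell order.
#' @param C correspondence matrix (n x n).
#' @param mu trade-off in `[0, 1]`; 0.5 gives both losses equal weight.
#' @return a `joint_graph` list: `assembled`, `degree` (vector of row
#'   sums), `laplacian`, `mu`, `n`, `isolated` (indices with zero degree).
#' @export
build_joint <- function(W_e, W_t, C, mu = 0.5) {
  n <- nrow(W_e)
  if (!all(dim(W_e) == n, dim(W_t) == n, dim(C) == n))
    stop("W_e, W_t and C must all be n x n over the same cells")
  if (!is.null(rownames(W_e)) && !is.null(rownames(W_t)) &&
      !identical(rownames(W_e), rownames(W_t)))
    stop("W_e and W_t node ids differ")
  stopifnot(mu >= 0, mu <= 1)
  W_e <- unclass(W_e); W_t <- unclass(W_t); C <- unclass(C)
  A <- rbind(cbind(mu * W_e, (1 - mu) * C),
             cbind((1 - mu) * t(C), mu * W_t))
  deg <- rowSums(A)
  L <- -A
  diag(L) <- diag(L) + deg
  isolated <- which(deg == 0)
  if (length(isolated))
    message(length(isolated), " isolated node(s) in the joint graph")
  structure(list(assembled = A, degree = deg, laplacian = L, mu = mu, n = n,
                 isolated = isolated),
            class = "joint_graph")
}

#' @export
print.joint_graph <- function(x, ...) {
  cat(sprintf("joint_graph: 2n = %d nodes, mu = %g, %d isolated\n",
              2 * x$n, x$mu, length(x$isolated)))
  invisible(x)
}

#' Export a graph as an edge list
#'
#' @param adj adjacency matrix.
#' @param path output TSV path (columns i, j, weight; upper triangle only).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(adj, path) {
  idx <- which(upper.tri(adj) & adj != 0, arr.ind = TRUE)
  utils::write.table(data.frame(i = idx[, 1], j = idx[, 2],
                                weight = adj[idx]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
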