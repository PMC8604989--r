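# shared fixtures and independent oracles

# strip the class/modality decoration for value comparisons
bare <- function(m) {
  a <- unclass(m)
  attr(a, "modality") <- NULL
  a
}

fm <- function(x, modality = "expression", ids = rownames(x),
               feats = colnames(x)) {
  x <- as.matrix(x)
  if (is.null(ids)) ids <- sprintf("c%02d", seq_len(nrow(x)))
  if (is.null(feats)) feats <- sprintf("f%02d", seq_len(ncol(x)))
  feature_matrix(x, ids, feats, modality)
}

random_dataset <- function(n, d1 = 4, d2 = 5, seed = 1) {
  set.seed(seed)
  mm_dataset(fm(matrix(rnorm(n * d1), n), "electrophysiology"),
             fm(matrix(rnorm(n * d2), n), "expression"))
}

# standardized synthetic dataset at the default study conditions
std_synth <- function(config = synth_config(seed = 1)) {
  ds <- simulate_patchseq(config)
  out <- mm_dataset(standardize_features(ds$e), standardize_features(ds$t),
                    ds$labels)
  attr(out, "truth") <- attr(ds, "truth")
  out
}

# brute-force joint-graph loss: half the weighted sum of squared embedding
# gaps over ordered node pairs (independent of joint_loss)
brute_loss <- function(A, Q) {
  tot <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(A))) {
    if (A[i, j] != 0) tot <- tot + A[i, j] * sum((Q[i, ] - Q[j, ])^2)
  }
  tot / 2
}

# dense-pencil oracle: minimum loss over exhaustive d-subsets of the
# non-trivial generalized eigenvectors of (L, D)
oracle_min_loss <- function(A, d, eig_tol = 1e-8) {
  deg <- rowSums(A)
  L <- diag(deg) - A
  s <- 1 / sqrt(deg)
  M <- (t(L * s) * s)
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  vals <- rev(e$values)
  vecs <- (s * e$vectors)[, rev(seq_along(vals)), drop = FALSE]
  keep <- which(vals > eig_tol)
  best <- Inf
  for (sub in utils::combn(keep, d, simplify = FALSE)) {
    l <- brute_loss(A, vecs[, sub, drop = FALSE])
    if (l < best) best <- l
  }
  best
}

# connected components by breadth-first search (independent of any package)
bfs_components <- function(A) {
  n <- nrow(A)
  comp <- rep(0L, n)
  k <- 0L
  for (start in seq_len(n)) {
    if (comp[start] > 0) next
    k <- k + 1L
    queue <- start
    comp[start] <- k
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(A[v, ] != 0 & comp == 0L)
      comp[nb] <- k
      queue <- c(queue, nb)
    }
  }
  k
}

# exhaustive two-sided rank-sum p over all group-1 index subsets,
# written independently of the package's combn-based path (bitmask loop)
brute_wilcoxon_p <- function(x, idx1) {
  n <- length(x)
  n1 <- length(idx1)
  r <- rank(x)
  mu <- n1 * mean(r)
  obs <- abs(sum(r[idx1]) - mu)
  count <- 0L; total <- 0L
  for (mask in 0:(2^n - 1)) {
    bits <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(bits) != n1) next
    total <- total + 1L
    if (abs(sum(r[bits]) - mu) >= obs - 1e-9) count <- count + 1L
  }
  count / total
}
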