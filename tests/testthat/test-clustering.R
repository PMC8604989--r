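test_that("combined features concatenate both latent views in cell order", {
  emb <- list(e_coords = matrix(1:6, 2, 3,
                                dimnames = list(c("a", "b"), NULL)),
              t_coords = matrix(7:12, 2, 3,
                                dimnames = list(c("a", "b"), NULL)))
  f <- combined_features(emb)
  expect_equal(colnames(f), c("dim_e1", "dim_e2", "dim_e3",
                              "dim_t1", "dim_t2", "dim_t3"))
  expect_equal(rownames(f), c("a", "b"))
  expect_equal(unname(unclass(f)[2, ]), c(2, 4, 6, 8, 10, 12))
})

test_that("single-component fit recovers the closed-form MLE", {
  set.seed(1)
  x <- fm(matrix(rnorm(200), 50, 4), "latent")
  fit <- fit_gmm(x, K = 1, seed = 1)
  expect_equal(unname(fit$means[1, ]), unname(colMeans(x)), tolerance = 1e-8)
  n <- nrow(x)
  mle_cov <- cov(unclass(x)) * (n - 1) / n
  reg <- 1e-6 * mean(apply(x, 2, var))      # documented regularization
  expect_equal(fit$covariances[[1]], mle_cov + diag(reg, 4),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fit$weights, 1)
})

test_that("EM separates a well-separated 1-D mixture and is monotone", {
  set.seed(2)
  x <- fm(matrix(c(rnorm(100, 0, 0.1), rnorm(100, 10, 0.1))), "latent")
  fit <- fit_gmm(x, K = 2, seed = 3)
  expect_equal(sort(fit$means[, 1]), c(0, 10), tolerance = 0.05)
  tol <- 1e-8 * (1 + abs(fit$log_likelihood))
  expect_true(all(diff(fit$loglik_trace) >= -tol))
})

test_that("EM recovers planted 2-D mixtures and agrees with mclust", {
  aris <- numeric(10)
  for (s in 1:10) {
    set.seed(s)
    centers <- matrix(c(0, 0, 5, 0, 0, 5), 3, 2, byrow = TRUE)
    lab <- rep(1:3, each = 200)
    x <- centers[lab, ] + matrix(rnorm(1200, sd = 1), 600)
    f <- fm(x, "latent")
    best <- NULL
    for (r in 1:3) {
      g <- fit_gmm(f, 3, seed = 10 * s + r)
      if (is.null(best) || g$log_likelihood > best$log_likelihood) best <- g
    }
    asg <- assign_clusters(best, f)
    aris[s] <- mclust::adjustedRandIndex(asg$labels, lab)
    # means within 0.1 sd of the truth (after matching components)
    perm <- apply(best$means, 1, function(m)
      which.min(colSums((t(centers) - m)^2)))
    expect_equal(best$means, centers[perm, ], tolerance = 0.1,
                 ignore_attr = TRUE)
  }
  expect_true(all(aris >= 0.95))

  # independent route: mclust on one of the replicates reaches the same
  # partition as our EM
  set.seed(1)
  lab <- rep(1:3, each = 200)
  x <- matrix(c(0, 0, 5, 0, 0, 5), 3, 2, byrow = TRUE)[lab, ] +
    matrix(rnorm(1200), 600)
  ours <- assign_clusters(fit_gmm(fm(x, "latent"), 3, seed = 11),
                          fm(x, "latent"))
  mclustBIC <- mclust::mclustBIC   # Mclust resolves this in the caller
  mc <- mclust::Mclust(x, G = 3, modelNames = "VVV", verbose = FALSE)
  expect_gte(mclust::adjustedRandIndex(ours$labels, mc$classification), 0.98)
})

test_that("BIC selects the planted number of components", {
  set.seed(4)
  lab <- rep(1:4, each = 100)
  centers <- matrix(rnorm(8, sd = 10), 4, 2)
  x <- fm(centers[lab, ] + matrix(rnorm(800), 400), "latent")
  sel <- select_K_bic(x, 1:6, seed = 5)
  expect_equal(sel$K, 4)
  expect_equal(nrow(sel$bic_table), 6)
  expect_true(all(c("K", "loglik", "bic", "d_bic") %in%
                  names(sel$bic_table)))

  single <- fm(matrix(rnorm(400), 200, 2), "latent")
  expect_equal(select_K_bic(single, 1:4, seed = 6)$K, 1)
})

test_that("posterior assignment is normalized, calibrated and tie-stable", {
  model <- structure(list(K = 2, weights = c(0.5, 0.5),
                          means = matrix(c(0, 2), 2, 1),
                          covariances = list(matrix(1), matrix(1))),
                     class = "gmm_fit")
  f <- fm(matrix(c(1, 0, 2, -5)), "latent")
  asg <- assign_clusters(model, f)
  expect_equal(rowSums(asg$posteriors), rep(1, 4), tolerance = 1e-12)
  # x = 1 is equidistant between symmetric components
  expect_equal(asg$posteriors[1, ], c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(asg$labels[[1]], 1L)    # tie goes to the lower index

  # far-apart spherical components: a point at a mean is assigned there
  model2 <- structure(list(K = 2, weights = c(0.5, 0.5),
                           means = matrix(c(0, 0, 50, 50), 2, 2, byrow = TRUE),
                           covariances = list(diag(2), diag(2))),
                      class = "gmm_fit")
  asg2 <- assign_clusters(model2, fm(matrix(c(50, 50), 1), "latent"))
  expect_gt(asg2$posteriors[1, 2], 1 - 1e-10)
})

test_that("alternative clusterings recover obvious blobs deterministically", {
  set.seed(6)
  x <- fm(rbind(matrix(rnorm(100, 0, 0.3), 50),
                matrix(rnorm(100, 20, 0.3), 50)), "latent")
  lab <- rep(1:2, each = 50)
  for (m in c("kmedoid", "hierarchical")) {
    a <- alternative_clusterings(x, 2, m)
    expect_equal(mclust::adjustedRandIndex(a$labels, lab), 1)
    b <- alternative_clusterings(x, 2, m)
    expect_identical(a$labels, b$labels)
    expect_true(all(rowSums(a$posteriors) == 1))
  }
  singletons <- alternative_clusterings(x[1:5, ], 5, "kmedoid")
  expect_equal(length(unique(singletons$labels)), 5)
})

test_that("concordance reports contingency, majority fractions and ARI", {
  lab <- rep(c("A", "B"), each = 10)
  cl <- rep(1:2, each = 10)
  cc <- cluster_label_concordance(cl, lab)
  expect_equal(cc$ari, 1)
  expect_equal(unname(cc$max_fraction), c(1, 1))
  expect_equal(as.vector(cc$contingency), c(10, 0, 0, 10))

  set.seed(7)
  cc0 <- cluster_label_concordance(sample(1:5, 1000, TRUE),
                                   sample(1:5, 1000, TRUE))
  expect_lt(abs(cc0$ari), 0.02)
})
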