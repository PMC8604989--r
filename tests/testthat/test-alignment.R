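test_that("identical views with identity correspondence align exactly", {
  ds <- random_dataset(30, d1 = 5, d2 = 5, seed = 2)
  ds$t <- feature_matrix(unclass(ds$e), rownames(ds$e), colnames(ds$t),
                         "expression")
  fit <- manifold_align(ds, "nma", d = 2)
  expect_lt(max(abs(fit$e_coords - fit$t_coords)), 1e-8)
  expect_lt(max(paired_distance(fit, FALSE)$paired_distances), 1e-8)
})

test_that("NMA loss matches the dense-pencil oracle and satisfies Q'DQ = I", {
  for (seed in 1:10) {
    n <- 10 + seed
    ds <- random_dataset(n, seed = 100 + seed)
    fit <- manifold_align(ds, "nma", d = 2)
    W_e <- knn_graph(ds$e, 2)
    W_t <- knn_graph(ds$t, 2)
    jg <- build_joint(W_e, W_t, diag(n), mu = 0.5)
    Q <- rbind(fit$e_coords, fit$t_coords)
    # loss equals the brute-force functional of the returned coordinates
    expect_equal(fit$loss, brute_loss(jg$assembled, Q), tolerance = 1e-10)
    # and the exhaustive eigenvector-subset minimum
    expect_equal(fit$loss, oracle_min_loss(jg$assembled, 2),
                 tolerance = 1e-8)
    G <- crossprod(Q, jg$degree * Q)
    expect_lt(max(abs(G - diag(2))), 1e-6)
  }
})

test_that("NMA beats random D-orthonormal embeddings", {
  for (seed in 1:10) {
    n <- sample(10:30, 1)
    ds <- random_dataset(n, seed = 200 + seed)
    fit <- manifold_align(ds, "nma", d = 2)
    jg <- build_joint(knn_graph(ds$e, 2), knn_graph(ds$t, 2), diag(n), 0.5)
    set.seed(seed)
    for (r in 1:100) {
      G <- matrix(rnorm(2 * n * 2), 2 * n)
      # D-orthonormalize via Gram-Schmidt in the D inner product
      G[, 1] <- G[, 1] / sqrt(sum(jg$degree * G[, 1]^2))
      G[, 2] <- G[, 2] - sum(jg$degree * G[, 1] * G[, 2]) * G[, 1]
      G[, 2] <- G[, 2] / sqrt(sum(jg$degree * G[, 2]^2))
      expect_gte(joint_loss(jg, G), fit$loss - 1e-10)
    }
  }
})

test_that("LMA embeds linearly related views and never beats NMA", {
  # the t view is an orthogonal rotation of the e view: both kNN graphs
  # coincide, an exact linear correspondence exists, and LMA finds it
  set.seed(4)
  Xe <- matrix(rnorm(160), 40, 4)
  R <- qr.Q(qr(matrix(rnorm(16), 4)))
  ds <- mm_dataset(fm(Xe, "electrophysiology"), fm(Xe %*% R, "expression"))
  lma <- manifold_align(ds, "lma", d = 2)
  expect_lt(paired_distance(lma, FALSE)$mean_paired_distance, 1e-6)
  nma <- manifold_align(ds, "nma", d = 2)
  expect_gte(lma$loss, nma$loss - 1e-10)

  # the parametric map reproduces training coordinates
  pr <- predict(lma, ds)
  expect_equal(pr$e_coords, unname(lma$e_coords), ignore_attr = TRUE)
  expect_equal(pr$t_coords, unname(lma$t_coords), ignore_attr = TRUE)
})

test_that("CCA recovers known canonical correlations", {
  ds <- mm_dataset(fm(matrix(1:6, 6, 1), "electrophysiology"),
                   fm(matrix(2 * (1:6), 6, 1)))
  fit <- manifold_align(ds, "cca", d = 1)
  expect_equal(fit$details$canonical_cors[1], 1, tolerance = 1e-4)

  # bivariate construction with true canonical correlation 0.9
  set.seed(7)
  n <- 2000
  z <- rnorm(n)
  x <- z + rnorm(n, sd = sqrt(1 / 0.9 - 1))
  y <- z + rnorm(n, sd = sqrt(1 / 0.9 - 1))
  # cor(x, y) = 0.9 when each shares sqrt(0.9) correlation with z
  ds2 <- mm_dataset(fm(cbind(x, rnorm(n)), "electrophysiology"),
                    fm(cbind(y, rnorm(n))))
  fit2 <- manifold_align(ds2, "cca", d = 1)
  expect_equal(fit2$details$canonical_cors[1], 0.9, tolerance = 0.03)

  # independent views: all canonical correlations small
  ds3 <- random_dataset(1000, d1 = 5, d2 = 5, seed = 12)
  fit3 <- manifold_align(ds3, "cca", d = 5)
  expect_lt(max(fit3$details$canonical_cors), 0.2)

  # cross-check the leading correlation against the base-R oracle
  cc <- cancor(unclass(ds2$e), unclass(ds2$t))
  expect_equal(fit2$details$canonical_cors[1], cc$cor[1], tolerance = 1e-3)
})

test_that("RRR reduces to OLS at full rank and solves exact low-rank maps", {
  set.seed(3)
  Xt <- matrix(rnorm(50 * 4), 50)
  b <- rnorm(4); a <- rnorm(3)
  Xe <- Xt %*% b %*% t(a)
  ds <- mm_dataset(fm(Xe, "electrophysiology"), fm(Xt))
  fit <- manifold_align(ds, "rrr", d = 1)
  expect_lt(max(abs(fit$e_coords - fit$t_coords)), 1e-8)

  # d = min(d1, d2): truncation is a no-op, fitted values are full OLS
  Xe2 <- Xt %*% matrix(rnorm(12), 4, 3) + matrix(rnorm(150), 50, 3)
  ds2 <- mm_dataset(fm(Xe2, "electrophysiology"), fm(Xt))
  fit2 <- manifold_align(ds2, "rrr", d = 3)
  X <- scale(Xt, scale = FALSE); Y <- scale(Xe2, scale = FALSE)
  ols_fitted <- X %*% qr.solve(X, Y)
  expect_equal(X %*% fit2$projections$B, ols_fitted, tolerance = 1e-8,
               ignore_attr = TRUE)

  # hand-checkable normal equations on a tiny case
  Xt3 <- matrix(c(1, 2, 3, 1, 1, 2), 3)
  Xe3 <- matrix(c(2, 4, 7, 0, 1, 1), 3)
  ds3 <- mm_dataset(fm(Xe3, "electrophysiology"), fm(Xt3))
  fit3 <- manifold_align(ds3, "rrr", d = 2)
  Xc <- scale(Xt3, scale = FALSE); Yc <- scale(Xe3, scale = FALSE)
  expect_equal(fit3$projections$B, solve(crossprod(Xc), crossprod(Xc, Yc)),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("PCA control embeds each view independently", {
  line <- fm(cbind(1:10, 2 * (1:10)), "electrophysiology")
  p <- pca_embed(line, 2)
  expect_equal(p$var_explained[1], 1, tolerance = 1e-12)
  expect_true(all(diff(p$var_explained) <= 1e-12))

  toy <- fm(matrix(c(1, 2, 4, 1, 3, 5), 3))
  p2 <- pca_embed(toy, 2)
  S <- cov(unclass(toy))
  ev <- eigen(S, symmetric = TRUE)
  # scores match projection onto the covariance eigenvectors (up to sign)
  oracle <- scale(unclass(toy), scale = FALSE) %*% ev$vectors
  expect_equal(abs(unname(p2$scores)), abs(unname(oracle)),
               tolerance = 1e-10)
})

test_that("alignment is reproducible run to run", {
  ds <- std_synth(synth_config(n_cells = 100, d2 = 40, seed = 4))
  f1 <- manifold_align(ds, "nma")
  f2 <- manifold_align(ds, "nma")
  expect_identical(f1$e_coords, f2$e_coords)
  expect_error(manifold_align(ds, "nma", d = 300), "non-trivial")
})
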