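test_that("kNN graph matches the hand-derived toy and the tie rule", {
  m <- fm(matrix(c(0, 1, 2, 10), 4, 1), "electrophysiology")
  adj <- knn_graph(m, k = 1)
  # node 2 is tied between nodes 1 and 3; the lower index wins, and the
  # union symmetrization still yields the chain 1-2, 2-3, 3-4
  expected <- matrix(0, 4, 4)
  expected[cbind(c(1, 2, 3), c(2, 3, 4))] <- 1
  expected <- expected + t(expected)
  dimnames(expected) <- dimnames(adj)
  expect_equal(adj, expected)

  two <- knn_graph(fm(matrix(c(0, 5), 2, 1)), k = 1)
  expect_equal(unname(two), matrix(c(0, 1, 1, 0), 2))
  expect_error(knn_graph(two_cells <- fm(matrix(rnorm(4), 2)), k = 2),
               "smaller")
})

test_that("kNN graphs are symmetric, hollow and binary", {
  for (seed in 1:5) {
    set.seed(seed)
    adj <- knn_graph(fm(matrix(rnorm(60), 20, 3)), k = sample(1:5, 1))
    expect_lt(max(abs(adj - t(adj))), 1e-12)
    expect_true(all(diag(adj) == 0))
    expect_true(all(adj %in% c(0, 1)))
  }
})

test_that("correspondence construction validates pairs", {
  C <- identity_correspondence(3)
  expect_equal(unclass(C), diag(3), ignore_attr = TRUE)
  expect_equal(attr(C, "mask_fraction"), 1)

  half <- correspondence_from_pairs(4, cbind(c(1, 3), c(1, 3)))
  expect_true(all(rowSums(half) %in% c(0, 1)))
  expect_equal(sum(half), 2)
  expect_equal(attr(half, "mask_fraction"), 0.5)

  perm <- correspondence_from_pairs(2, rbind(c(1, 2), c(2, 1)))
  expect_equal(unclass(perm), matrix(c(0, 1, 1, 0), 2), ignore_attr = TRUE)

  expect_error(correspondence_from_pairs(3, rbind(c(1, 1), c(1, 2))),
               "duplicate")
  expect_error(correspondence_from_pairs(3, rbind(c(1, 4))), "range")
})

test_that("joint graph assembly matches the hand-built path-graph case", {
  P3 <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3)
  jg <- build_joint(P3, P3, diag(3), mu = 0.5)
  expected <- rbind(cbind(0.5 * P3, 0.5 * diag(3)),
                    cbind(0.5 * diag(3), 0.5 * P3))
  expect_equal(jg$assembled, expected)
  expect_equal(jg$degree, rowSums(expected))
  expect_lt(max(abs(rowSums(jg$laplacian))), 1e-10)

  # limit cases for the trade-off
  jg0 <- build_joint(P3, P3, diag(3), mu = 0)
  expect_true(all(jg0$assembled[1:3, 1:3] == 0))
  expect_true(all(jg0$assembled[4:6, 4:6] == 0))
  jg1 <- suppressMessages(build_joint(P3, P3, diag(3), mu = 1))
  expect_true(all(jg1$assembled[1:3, 4:6] == 0))

  expect_error(build_joint(P3, matrix(0, 2, 2), diag(3), 0.5), "n x n")
})

test_that("the path-graph pencil has generalized eigenvalues 0, 1, 2", {
  # 1-D points 0,1,2 with k=1 give exactly the path graph in both views;
  # with mu = 1 the joint pencil is two decoupled copies of (L_P3, D_P3),
  # whose non-trivial eigenvalues are 1 and 2 (v = (1,0,-1), (1,-1,1))
  m <- fm(matrix(c(0, 1, 2), 3, 1), "electrophysiology")
  ds <- mm_dataset(m, fm(matrix(c(0, 1, 2), 3, 1)))
  fit <- suppressMessages(
    manifold_align(ds, "nma", k = 1, d = 4, mu = 1))
  expect_equal(fit$eigenvalues, c(1, 1, 2, 2), tolerance = 1e-10)
})

test_that("joint Laplacians are positive semidefinite", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(4:12, 1)
    ds <- random_dataset(n, seed = seed)
    W_e <- knn_graph(ds$e, 2)
    W_t <- knn_graph(ds$t, 2)
    jg <- build_joint(W_e, W_t, diag(n), mu = runif(1, 0.2, 0.8))
    expect_gte(min(eigen(jg$laplacian, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-8)
  }
})

test_that("zero generalized eigenvalues count connected components", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(10:25, 1)
    # two or three well-separated point groups -> disconnected kNN graph
    groups <- sample(2:3, 1)
    x <- matrix(rnorm(n * 2, sd = 0.1), n) +
      100 * matrix(sample(groups, n, TRUE), n, 2)
    adj <- knn_graph(fm(x), k = 2)
    jg <- suppressMessages(build_joint(adj, adj, diag(n), mu = 1))
    s <- 1 / sqrt(jg$degree)
    vals <- eigen(t(jg$laplacian * s) * s, symmetric = TRUE,
                  only.values = TRUE)$values
    expect_equal(sum(vals < 1e-8), 2 * bfs_components(adj))
  }
})

test_that("edge lists export the non-zero upper triangle", {
  p <- withr::local_tempfile(fileext = ".tsv")
  P3 <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3)
  write_edge_list(P3, p)
  el <- read.table(p, header = TRUE)
  expect_equal(el, data.frame(i = 1:2, j = 2:3, weight = c(1, 1)))
})
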