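test_that("exact rank-sum p matches the textbook example and wilcox.test", {
  x <- fm(matrix(c(1, 2, 3, 4, 5, 6)), "expression")
  lab <- c(1, 1, 1, 2, 2, 2)
  tab <- wilcoxon_de(x, lab, cluster = 1)
  # rank sum 6 is the extreme arrangement: 2 of C(6,3)=20 two-sided
  expect_equal(tab$wilcoxon_p, 0.1)
  expect_equal(tab$auc, 0)               # group 1 uniformly smaller
  ref <- wilcox.test(c(1, 2, 3), c(4, 5, 6))$p.value
  expect_equal(tab$wilcoxon_p, ref)
})

test_that("exact enumeration agrees with a brute-force oracle under ties", {
  set.seed(1)
  for (case in 1:50) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    vals <- sample(1:5, n1 + n2, replace = TRUE)   # heavy ties
    lab <- c(rep(1, n1), rep(2, n2))
    x <- fm(matrix(as.numeric(vals)), "expression")
    if (sd(vals) == 0) next
    tab <- suppressWarnings(wilcoxon_de(x, lab, cluster = 1))
    expect_equal(tab$wilcoxon_p, brute_wilcoxon_p(vals, seq_len(n1)),
                 tolerance = 1e-12)
  }
})

test_that("large-sample p uses the tie-corrected normal approximation", {
  set.seed(2)
  x <- c(rnorm(30), rnorm(40, 1))
  x <- round(x, 1)                               # induce ties
  lab <- c(rep(1, 30), rep(2, 40))
  tab <- wilcoxon_de(fm(matrix(x)), lab, cluster = 1)
  ref <- wilcox.test(x[lab == 1], x[lab == 2], exact = FALSE,
                     correct = FALSE)$p.value
  expect_equal(tab$wilcoxon_p, ref, tolerance = 1e-10)
})

test_that("AUC equals U / (n1 n2) and hits the extremes", {
  set.seed(3)
  for (case in 1:20) {
    n1 <- sample(3:15, 1); n2 <- sample(3:15, 1)
    x <- rnorm(n1 + n2)
    lab <- sample(c(rep(1, n1), rep(2, n2)))
    tab <- wilcoxon_de(fm(matrix(x)), lab, cluster = 1)
    U <- unname(wilcox.test(x[lab == 1], x[lab == 2])$statistic)
    expect_equal(tab$auc, U / (n1 * n2), tolerance = 1e-12)
  }
  sep <- c(5, 6, 7, 1, 2, 3)
  tab <- wilcoxon_de(fm(matrix(sep)), c(1, 1, 1, 2, 2, 2), 1)
  expect_equal(tab$auc, 1)

  const <- wilcoxon_de(fm(matrix(rep(2, 8))), rep(1:2, each = 4), 1)
  expect_equal(const$wilcoxon_p, 1)
  expect_equal(const$auc, 0.5)
})

test_that("BH adjustment matches the hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.1)), c(0.03, 0.03, 0.1))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)))
})

test_that("marker selection is strict at the threshold and sign-filtered", {
  tab <- data.frame(feature = c("g1", "g2", "g3"), cluster = 1,
                    mean_in = 1, mean_out = 0,
                    log_fc = c(1, 1, -1), auc = 0.9,
                    wilcoxon_p = c(0.001, 0.01, 0.001),
                    adj_p = c(0.005, 0.01, 0.005), significant = TRUE)
  out <- select_markers(tab, alpha = 0.01)
  expect_equal(out$cluster1, "g1")       # g2 at the boundary, g3 down
  expect_equal(select_markers(tab[0, ], 0.01), list())
})

test_that("planted markers are recovered with high precision and recall", {
  ds <- std_synth()
  truth <- attr(ds, "truth")
  tab <- wilcoxon_de_all(ds$t, truth$cluster_labels, alpha = 0.01)
  expect_true(all(tab$adj_p >= tab$wilcoxon_p - 1e-15))
  sets <- select_markers(tab, alpha = 0.01)
  truth_pairs <- unlist(lapply(seq_along(truth$marker_sets), function(k)
    paste0(k, ":", truth$marker_sets[[k]])))
  found_pairs <- unlist(lapply(names(sets), function(nm)
    paste0(sub("cluster", "", nm), ":", sets[[nm]])))
  expect_gte(mean(found_pairs %in% truth_pairs), 0.9)  # precision
  expect_gte(mean(truth_pairs %in% found_pairs), 0.9)  # recall
})

test_that("the adjusted-p threshold controls false discoveries under the null", {
  fractions <- vapply(1:10, function(s) {
    set.seed(s)
    x <- fm(matrix(rnorm(300 * 400), 300, 400), "expression")
    lab <- rep(1:2, length.out = 300)
    tab <- wilcoxon_de(x, lab, cluster = 1, alpha = 0.05)
    mean(tab$adj_p < 0.05)
  }, numeric(1))
  expect_lte(mean(fractions), 0.05)
})

test_that("representative e-features flag magnitude shifts", {
  set.seed(9)
  n <- 200
  lab <- rep(1:2, each = n / 2)
  f1 <- ifelse(lab == 1, sample(c(-1, 1), n, TRUE) * rnorm(n, 3), rnorm(n))
  e <- fm(cbind(burst = f1, flat = rep(0, n), noise = rnorm(n)),
          "electrophysiology")
  tab <- representative_efeatures(e, lab, alpha = 0.05)
  r1 <- tab[tab$cluster == 1 & tab$feature == "burst", ]
  expect_true(r1$significant && r1$log_fc > 0)
  expect_false(any(tab$significant[tab$feature == "flat"]))
  expect_true(all(tab$feature %in% colnames(e)))
})
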