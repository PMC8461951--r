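test_that("rank-1 data puts all variance on PC1", {
  u <- rnorm(6); v <- seq(1, 5)
  x <- outer(u, v) + 7
  dimnames(x) <- list(sprintf("F%d", 1:6), sprintf("S%d", 1:5))
  pc <- pca_explained_variance(x, n_components = 2)
  expect_equal(pc$fractions[1], 1)
  expect_equal(pc$fractions[2], 0, tolerance = 1e-12)
})

test_that("explained-variance fractions equal the covariance eigendecomposition", {
  set.seed(41)
  x <- matrix(rnorm(30), nrow = 6,
              dimnames = list(sprintf("F%d", 1:6), sprintf("S%d", 1:5)))
  pc <- pca_explained_variance(x, n_components = 3)
  xc <- x - rowMeans(x)                 # center per feature
  ev <- eigen(crossprod(xc) / (ncol(x) - 1), symmetric = TRUE)$values
  expect_equal(pc$fractions, (ev / sum(ev))[1:3], tolerance = 1e-10)
  expect_true(all(diff(pc$fractions) <= 1e-12))
  expect_true(sum(pc$fractions) <= 1 + 1e-12)
})

test_that("PCA is deterministic in sign and invariant to sample order", {
  set.seed(42)
  x <- matrix(rnorm(80), nrow = 8,
              dimnames = list(sprintf("F%d", 1:8), sprintf("S%02d", 1:10)))
  pc1 <- pca_explained_variance(x)
  # sign convention: largest-magnitude loading positive
  for (j in 1:3) {
    expect_gt(pc1$loadings[which.max(abs(pc1$loadings[, j])), j], 0)
  }
  perm <- sample(ncol(x))
  pc2 <- pca_explained_variance(x[, perm])
  expect_equal(pc1$fractions, pc2$fractions, tolerance = 1e-10)
  # duplicated sample -> identical score rows
  xd <- cbind(x, S11 = x[, 1])
  pcd <- pca_explained_variance(xd)
  expect_equal(pcd$scores["S11", ], pcd$scores["S01", ], ignore_attr = TRUE)
  expect_error(pca_explained_variance(x, n_components = 9), "exceeds")
})

test_that("sample clustering merges identical samples at height zero and recovers groups", {
  set.seed(43)
  x <- matrix(rnorm(60), nrow = 10)
  x <- cbind(x, x[, 1])
  dimnames(x) <- list(sprintf("F%d", 1:10), sprintf("S%d", 1:7))
  hc <- cluster_samples(x, scale_features = FALSE)
  expect_equal(hc$height[1], 0)
  expect_setequal(hc$labels[-hc$merge[1, ]], c("S1", "S7"))

  cc <- generate_case_control(case_control_spec(
    12, 12, 300, signature_features = 1:60, mean_fc = 1.6,
    fc_dispersion = 0, noise_sd = 0.25, seed = 44))
  sub <- cc$exprs[1:60, ]
  hc2 <- cluster_samples(sub)
  cut2 <- cut_clusters(hc2, k = 2)
  expect_gte(adjusted_rand(cut2, cc$samples$group), 0.8)
})

test_that("exact Mann-Whitney equals enumeration across random small fixtures", {
  set.seed(45)
  for (i in 1:60) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    vals <- if (i %% 3 == 0) {
      sample(1:5, n1 + n2, replace = TRUE)      # heavy ties
    } else {
      rnorm(n1 + n2)
    }
    lab <- rep(c("a", "b"), c(n1, n2))
    gt <- two_group_test(vals, lab)
    expect_true(gt$exact)
    expect_equal(gt$p, oracle_mw_exact(vals[lab == "a"], vals[lab == "b"]),
                 tolerance = 1e-12, label = sprintf("fixture %d", i))
  }
})

test_that("exact path agrees with wilcox.test on tie-free data", {
  set.seed(46)
  for (i in 1:20) {
    v1 <- rnorm(6); v2 <- rnorm(7)
    gt <- two_group_test(c(v1, v2), rep(c("a", "b"), c(6, 7)))
    wt <- stats::wilcox.test(v1, v2, exact = TRUE)
    expect_equal(gt$p, wt$p.value, tolerance = 1e-12)
    expect_equal(gt$statistic, unname(wt$statistic))
  }
})

test_that("identical group multisets give p = 1; constant data warns", {
  v <- c(1, 2, 3, 4)
  gt <- two_group_test(c(v, v), rep(c("a", "b"), each = 4))
  expect_equal(gt$p, 1)
  expect_warning(gt2 <- two_group_test(rep(5, 8), rep(c("a", "b"), each = 4)),
                 "constant")
  expect_equal(gt2$p, 1)
})

test_that("a large planted shift is detected at p < 0.001 with normality recorded", {
  mk <- generate_serum_markers(
    group_means = c(axSpA = 18, HC = 9), group_sds = c(axSpA = 0.35, HC = 0.35),
    group_ns = c(axSpA = 29L, HC = 11L), distribution = "lognormal", seed = 47
  )
  gt <- two_group_test(mk$value, mk$group)
  expect_lt(gt$p, 0.001)
  expect_false(gt$exact)
  tt <- two_group_test(log(mk$value), mk$group, test = "t_welch", normality_gate = TRUE)
  expect_s3_class(tt$normality, "data.frame")
  expect_equal(nrow(tt$normality), 2L)
  expect_true(all(c("W", "p", "normal_at_0.05") %in% names(tt$normality)))
})

test_that("Kruskal-Wallis handles the degenerate case and flags only the shifted group", {
  expect_equal(suppressWarnings(multi_group_test(rep(3, 9), rep(c("a", "b", "c"), 3)))$p, 1)
  set.seed(48)
  vals <- c(rnorm(10), rnorm(10), rnorm(10, mean = 4))
  lab <- rep(c("g1", "g2", "g3"), each = 10)
  gt <- multi_group_test(vals, lab)
  expect_lt(gt$p, 0.001)
  ph <- gt$posthoc
  expect_equal(nrow(ph), 3L)
  flagged <- ph[ph$p_adj < 0.05, ]
  expect_setequal(
    apply(flagged[, c("group1", "group2")], 1, function(r) paste(sort(r), collapse = "-")),
    c("g1-g3", "g2-g3")
  )
  expect_error(multi_group_test(c(1, 2, 3, 4, 5), c("a", "a", "b", "b", "c")),
               "< 2 samples")
  expect_error(multi_group_test(rnorm(8), rep(c("a", "b"), 4)), ">= 3 groups")
})

test_that("Kruskal-Wallis and Mann-Whitney agree on two-group rejection decisions", {
  set.seed(49)
  agree <- logical(200)
  for (i in 1:200) {
    shift <- sample(c(0, 0.4, 0.9), 1)
    v <- c(rnorm(20), rnorm(20, mean = shift))
    lab <- rep(c("a", "b"), each = 20)
    p_mw <- two_group_test(v, lab)$p
    p_kw <- stats::kruskal.test(v, factor(lab))$p.value
    agree[i] <- (p_mw < 0.05) == (p_kw < 0.05)
  }
  expect_true(all(agree))
})
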