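test_that("quantile normalization matches the hand-computed rank/mean construction", {
  # 4x3 integer toy with a within-column tie; hand computation:
  # sorted cols: (1,2,5,8), (2,3,3,6), (1,4,4,9) -> mean order stats
  # mu = (4/3, 3, 4, 23/3)
  x <- matrix(c(5, 1, 8, 2,
                3, 3, 6, 2,
                4, 9, 1, 4), nrow = 4,
              dimnames = list(sprintf("F%d", 1:4), sprintf("S%d", 1:3)))
  q <- quantile_normalize(x)
  mu <- c(4 / 3, 3, 4, 23 / 3)
  expect_equal(unname(q[, 1]), c(mu[3], mu[1], mu[4], mu[2])) # 5,1,8,2
  # column 2 has the tie 3,3 at sorted positions 2,3 -> both get mean(mu[2:3])
  expect_equal(unname(q[, 2]), c(mean(mu[2:3]), mean(mu[2:3]), mu[4], mu[1]))
  # column 3 ties 4,4 at sorted positions 2,3
  expect_equal(unname(q[, 3]), c(mean(mu[2:3]), mu[4], mu[1], mean(mu[2:3])))
})

test_that("columns that are permutations of each other are fixed points", {
  v <- c(2.2, 5.5, 1.1, 7.7, 3.3)
  x <- cbind(S1 = v, S2 = sample(v), S3 = rev(v))
  rownames(x) <- sprintf("F%d", 1:5)
  q <- quantile_normalize(x)
  expect_equal(q, x, ignore_attr = TRUE)
})

test_that("normalization equalizes all sample distributions and is idempotent", {
  set.seed(4)
  x <- matrix(rnorm(600, mean = rep(c(5, 7, 9), each = 200), sd = rep(1:3, each = 200)),
              ncol = 3, dimnames = list(sprintf("F%03d", 1:200), sprintf("S%d", 1:3)))
  q <- quantile_normalize(x)
  s <- apply(q, 2, sort)
  expect_identical(s[, 1], s[, 2])
  expect_identical(s[, 1], s[, 3])
  expect_equal(quantile_normalize(q), q, ignore_attr = TRUE)
})

test_that("normalization agrees with limma on tie-free data and rejects non-finite cells", {
  skip_if_not_installed("limma")
  set.seed(5)
  x <- matrix(rnorm(500), ncol = 5,
              dimnames = list(sprintf("F%03d", 1:100), sprintf("S%d", 1:5)))
  expect_equal(unname(quantile_normalize(x)[, ]),
               unname(limma::normalizeQuantiles(x)), tolerance = 1e-12)
  x[3, 2] <- NA
  expect_error(quantile_normalize(x), "non-finite.*F003, S2")
})

test_that("signature extraction preserves order and reports missing features", {
  comp <- generate_compendium(default_compendium_spec(n_features = 960, seed = 2))
  sig <- c(sprintf("F%04d", 950:1), sprintf("MISSING_%d", 1:7))   # 957 requested
  sub <- extract_signature_submatrix(comp, sig)
  expect_equal(nrow(sub$exprs), 950L)
  expect_equal(rownames(sub$exprs), sprintf("F%04d", 950:1))
  expect_equal(sub$n_missing, 7L)
  expect_setequal(sub$missing, sprintf("MISSING_%d", 1:7))
  expect_error(extract_signature_submatrix(comp, c("X1", "X2")), "nothing to map")
  # overlap equals plain set intersection
  set.seed(6)
  rand <- sample(c(rownames(comp$exprs), sprintf("NO_%02d", 1:50)), 100)
  sub2 <- extract_signature_submatrix(comp, rand)
  expect_setequal(rownames(sub2$exprs), intersect(rand, rownames(comp$exprs)))
})

test_that("gene-gene correlation matches the textbook formula and flags flat features", {
  set.seed(7)
  m <- matrix(rnorm(30), nrow = 5,
              dimnames = list(sprintf("F%d", 1:5), sprintf("S%d", 1:6)))
  cc <- gene_gene_correlation(m)
  expect_equal(diag(cc$R), rep(1, 5), ignore_attr = TRUE)
  expect_equal(cc$R, t(cc$R))
  for (i in 1:5) for (j in 1:5) {
    expect_equal(cc$R[i, j], oracle_pearson(m[i, ], m[j, ]), tolerance = 1e-12)
  }
  # a feature against its negation
  m2 <- rbind(m, F6 = -m[1, ])
  expect_equal(gene_gene_correlation(m2)$R["F1", "F6"], -1)
  # zero-variance feature excluded with a report
  m3 <- rbind(m, FLAT = rep(3, 6))
  cc3 <- gene_gene_correlation(m3)
  expect_equal(cc3$dropped, "FLAT")
  expect_false("FLAT" %in% rownames(cc3$R))
  expect_error(gene_gene_correlation(m[, 1:2]), ">= 3")
})

test_that("correlations are invariant under per-feature affine transforms", {
  set.seed(8)
  m <- matrix(rnorm(48), nrow = 6,
              dimnames = list(sprintf("F%d", 1:6), sprintf("S%d", 1:8)))
  R1 <- gene_gene_correlation(m)$R
  m2 <- m
  m2[3, ] <- 5 * m[3, ] + 2   # positive affine rescale of one feature's row
  R2 <- gene_gene_correlation(m2)$R
  expect_equal(R1, R2, tolerance = 1e-12)
})

test_that("UPGMA merges identical rows first at height zero, ties to lowest index", {
  d <- matrix(c(0, 5, 5, 3,
                5, 0, 0, 4,
                5, 0, 0, 4,
                3, 4, 4, 0), nrow = 4)
  hc <- upgma(d)
  expect_equal(hc$merge[1, ], c(-2L, -3L))
  expect_equal(hc$height[1], 0)
  # exact tie between pairs (1,4)=3 never beats (2,3)=0; next merge joins 1 and 4
  expect_equal(hc$merge[2, ], c(-1L, -4L))
  expect_true(all(diff(hc$height) >= 0))
})

test_that("UPGMA equals the brute-force oracle on random instances", {
  for (i in 1:40) {
    n <- sample(4:20, 1)
    d <- random_dist(n, seed = 1000 + i)
    hc <- upgma(d)
    or <- oracle_upgma(d)
    expect_identical(hc$merge, or$merge)
    expect_equal(hc$height, or$height, tolerance = 1e-9)
  }
})

test_that("correlation-matrix clustering recovers planted blocks at k = 4", {
  spec <- default_compendium_spec(seed = 13)       # 4 blocks, noise 0.25
  comp <- generate_compendium(spec)
  feats <- sprintf("F%04d", 1:160)
  res <- map_signature(feats, comp, k = 4)
  truth <- rep(1:4, each = 40)
  expect_gte(adjusted_rand(res$clusters, truth), 0.9)
  # both clustering representations are available
  res2 <- map_signature(feats, comp, k = 4, cluster_input = "one_minus_r")
  expect_gte(adjusted_rand(res2$clusters, truth), 0.9)
})

test_that("cut_clusters spans the trivial cuts and validates k", {
  hc <- upgma(random_dist(8, seed = 3))
  expect_equal(unname(cut_clusters(hc, k = 1)), rep(1L, 8))
  expect_equal(sort(unname(cut_clusters(hc, k = 8))), 1:8)
  expect_error(cut_clusters(hc, k = 9), "exceeds")
  expect_error(cut_clusters(hc), "supply")
})

test_that("display matrix is clipped to [-2, 2] and flat rows scale to zero", {
  set.seed(14)
  m <- rbind(matrix(rnorm(40, sd = 5), nrow = 4), FLAT = rep(1, 10))
  rownames(m)[1:4] <- sprintf("F%d", 1:4)
  colnames(m) <- sprintf("S%02d", 1:10)
  z <- scale_display(m)
  expect_true(all(z >= -2 & z <= 2))
  expect_equal(unname(z["FLAT", ]), rep(0, 10))
  expect_equal(unname(rowMeans(scale_display(m, clip = Inf))), rep(0, 5))
})

test_that("attribution scores equal the brute-force double loop and rank planted groups first", {
  spec <- compendium_spec(
    groups = c(granulo = 6, dc = 5, mono = 7), n_features = 30,
    blocks = list(block_spec(1:8, "granulo", 2), block_spec(9:16, "dc", 2)),
    noise_sd = 0.2, seed = 21
  )
  comp <- generate_compendium(spec)
  display <- scale_display(comp$exprs)
  clusters <- stats::setNames(rep(c(1L, 2L, 3L), c(8, 8, 14)), rownames(comp$exprs))
  att <- attribute_clusters(clusters, display, comp$samples$group)
  # brute-force double loop
  for (r in seq_len(nrow(att))) {
    members <- names(clusters)[clusters == att$cluster[r]]
    cols <- which(comp$samples$group == att$group[r])
    acc <- 0
    for (f in members) for (s in cols) acc <- acc + display[f, s]
    expect_equal(att$score[r], acc / (length(members) * length(cols)), tolerance = 1e-12)
  }
  top <- att[att$top, ]
  expect_equal(top$group[top$cluster == 1], "granulo")
  expect_equal(top$group[top$cluster == 2], "dc")
  expect_true(all(top$score[top$cluster %in% 1:2] > 0))
  # cluster 3 is flat across groups: all its scores near zero
  expect_lt(max(abs(att$score[att$cluster == 3])), 0.2)
})

test_that("attribution is invariant to permuting samples within a reference group", {
  comp <- generate_compendium(default_compendium_spec(seed = 5))
  display <- scale_display(comp$exprs[1:80, ])
  clusters <- stats::setNames(rep(1:2, each = 40), rownames(display))
  att1 <- attribute_clusters(clusters, display, comp$samples$group)
  perm <- unlist(lapply(unique(comp$samples$group), function(g) {
    idx <- which(comp$samples$group == g)
    sample(idx)
  }))
  att2 <- attribute_clusters(clusters, display[, perm], comp$samples$group[perm])
  expect_equal(att1, att2)
})

test_that("ordered heatmap export honors leaf order, clipping, and re-renders identically", {
  comp <- generate_compendium(default_compendium_spec(seed = 9))
  res <- map_signature(sprintf("F%04d", 1:120), comp, k = 3)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  png1 <- withr::local_tempfile(fileext = ".png")
  png2 <- withr::local_tempfile(fileext = ".png")
  m <- render_ordered_heatmap(res, png_path = png1, matrix_path = tsv)
  expect_equal(rownames(m), res$features[res$leaf_order])
  expect_true(all(m >= -2 & m <= 2))
  back <- suppressMessages(read_expression_matrix(tsv))
  expect_equal(back[, ], m[, ], tolerance = 0)
  render_ordered_heatmap(res, png_path = png2)
  expect_identical(readBin(png1, "raw", file.size(png1)),
                   readBin(png2, "raw", file.size(png2)))
})

test_that("dendrograms export as Newick readable by ape with the right leaves", {
  hc <- upgma(random_dist(10, seed = 12))
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(hc, f)
  tr <- ape::read.tree(f)
  expect_equal(sort(tr$tip.label), sort(hc$labels))
})
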