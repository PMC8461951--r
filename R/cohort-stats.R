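#' PCA explained-variance fractions for samples over signature features
#'
#' Principal component analysis of samples, with features as variables,
#' centered per feature (no scaling by default, matching common transcriptome
#' practice; set `scale. = TRUE` to scale). Fractions are eigenvalues of the
#' feature-centered covariance divided by total variance, reported for the
#' first `n_components` components together with sample scores. The sign of
#' each component is fixed so that its largest-magnitude loading is positive,
#' making the decomposition deterministic.
#'
#' @param x features x samples matrix (typically restricted to a signature).
#' @param n_components number of components to report (default 3).
#' @param scale. scale features to unit variance before decomposition.
#' @return list: `fractions` (length `n_components`, non-increasing, sums
#'   <= 1), `scores` (samples x components), `loadings` (features x
#'   components).
#' @export
pca_explained_variance <- function(x, n_components = 3L, scale. = FALSE) {
  stopifnot(is.matrix(x))
  if (ncol(x) < 3L) stop("PCA needs >= 3 samples", call. = FALSE)
  stopifnot_scalar_count(n_components, "n_components")
  if (n_components > min(dim(x))) {
    stop(sprintf("n_components = %d exceeds min(dim) = %d",
                 n_components, min(dim(x))), call. = FALSE)
  }
  check_finite_matrix(x, "expression matrix")
  if (scale.) {
    sds <- apply(x, 1L, stats::sd)
    x <- x[sds > 0, , drop = FALSE]
  }
  pc <- stats::prcomp(t(x), center = TRUE, scale. = scale.)
  fractions <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)]
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  loadings <- pc$rotation[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(n_components)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(fractions = fractions, scores = scores, loadings = loadings)
}

#' Hierarchically cluster samples over signature features
#'
#' Applies the same UPGMA engine used for gene-gene correlation clustering
#' to the samples: each sample is its vector of (optionally per-feature
#' z-scaled) signature values, and Euclidean distance between samples feeds
#' average linkage.
#'
#' @param x features x samples matrix.
#' @param scale_features z-scale each feature across samples first
#'   (default TRUE; zero-variance features are dropped).
#' @return an `hclust` object over samples (see [upgma()]).
#' @export
cluster_samples <- function(x, scale_features = TRUE) {
  stopifnot(is.matrix(x))
  if (ncol(x) < 2L) stop("need >= 2 samples", call. = FALSE)
  check_finite_matrix(x, "expression matrix")
  if (scale_features) {
    sds <- apply(x, 1L, stats::sd)
    x <- x[sds > 0, , drop = FALSE]
    x <- (x - rowMeans(x)) / apply(x, 1L, stats::sd)
  }
  upgma(stats::dist(t(x), method = "euclidean"))
}

# Exact two-sided Mann-Whitney p by enumeration of all group labelings.
# U is computed from average ranks, so ties contribute half-pairs; the null
# distribution of U under permutation is symmetric about n*m/2, so the
# two-sided p is the fraction of labelings at least as extreme as observed.
mw_exact <- function(v1, v2) {
  n1 <- length(v1); n2 <- length(v2)
  pooled <- c(v1, v2)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  mid <- n1 * n2 / 2
  dev_obs <- abs(u_obs - mid)
  u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
  p <- mean(abs(u_all - mid) >= dev_obs - 1e-9)
  list(U = u_obs, p = p)
}

#' Two-group test for serum-marker-style data
#'
#' Mann-Whitney U (default) or Welch t. The Mann-Whitney path is exact —
#' full enumeration of all labelings, valid under ties — whenever both
#' groups have at most 8 samples, and otherwise uses the normal
#' approximation with tie correction and continuity correction. With
#' `normality_gate = TRUE` a Shapiro-Wilk check (alpha 0.05 per group) is run
#' and its outcome is recorded alongside the result (the convention behind
#' "t test after confirmed normal distribution").
#'
#' @param values numeric vector.
#' @param labels group label per value; exactly two levels.
#' @param test `"mannwhitney"` or `"t_welch"`.
#' @param normality_gate run and record Shapiro-Wilk per group.
#' @return list of class `group_test_result`: test, statistic, p,
#'   group_sizes, exact (logical), normality (data.frame or NULL).
#' @export
two_group_test <- function(values, labels, test = c("mannwhitney", "t_welch"),
                           normality_gate = FALSE) {
  test <- match.arg(test)
  labels <- as.character(labels)
  stopifnot(length(values) == length(labels))
  lev <- unique(labels)
  if (length(lev) != 2L) stop("exactly two groups required", call. = FALSE)
  v1 <- values[labels == lev[1L]]
  v2 <- values[labels == lev[2L]]
  if (length(v1) < 2L || length(v2) < 2L) stop("need >= 2 per group", call. = FALSE)

  normality <- NULL
  if (normality_gate) {
    normality <- do.call(rbind, lapply(lev, function(g) {
      v <- values[labels == g]
      sw <- if (length(unique(v)) > 1L) stats::shapiro.test(v) else
        list(statistic = NA_real_, p.value = NA_real_)
      data.frame(group = g, W = unname(sw$statistic), p = sw$p.value,
                 normal_at_0.05 = !is.na(sw$p.value) && sw$p.value >= 0.05,
                 stringsAsFactors = FALSE)
    }))
  }

  if (stats::var(values) == 0) {
    warning("constant data in both groups; p = 1")
    res <- list(statistic = 0, p = 1, exact = TRUE)
  } else if (test == "mannwhitney") {
    if (length(v1) <= 8L && length(v2) <= 8L) {
      mw <- mw_exact(v1, v2)
      res <- list(statistic = mw$U, p = mw$p, exact = TRUE)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(v1, v2, exact = FALSE, correct = TRUE))
      res <- list(statistic = unname(wt$statistic), p = wt$p.value, exact = FALSE)
    }
  } else {
    tt <- stats::t.test(v1, v2)
    res <- list(statistic = unname(tt$statistic), p = tt$p.value, exact = FALSE)
  }

  structure(
    list(
      test = if (test == "mannwhitney") "Mann-Whitney U" else "Welch t",
      statistic = res$statistic, p = res$p,
      group_sizes = stats::setNames(c(length(v1), length(v2)), lev),
      exact = res$exact, normality = normality, posthoc = NULL
    ),
    class = "group_test_result"
  )
}

# Dunn's post-hoc pairwise z-tests on mean ranks after Kruskal-Wallis,
# with the standard tie correction; adjustment over all pairs.
dunn_posthoc <- function(values, labels, adjust = "bonferroni") {
  r <- rank(values)
  N <- length(values)
  lev <- unique(labels)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  rows <- list()
  for (i in seq_along(lev)) {
    for (j in seq_along(lev)) {
      if (j <= i) next
      ni <- sum(labels == lev[i]); nj <- sum(labels == lev[j])
      mi <- mean(r[labels == lev[i]]); mj <- mean(r[labels == lev[j]])
      se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ni + 1 / nj))
      z <- (mi - mj) / se
      rows[[length(rows) + 1L]] <- data.frame(
        group1 = lev[i], group2 = lev[j], z = z,
        p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = adjust)
  out
}

#' Kruskal-Wallis omnibus test with Dunn's post hoc
#'
#' Kruskal-Wallis H (with tie correction, via [stats::kruskal.test()])
#' across three or more groups, followed by Dunn's pairwise z-tests on mean
#' ranks. The post-hoc adjustment defaults to Bonferroni over all pairs
#' (`"holm"` and `"none"` are available).
#'
#' @param values numeric vector.
#' @param labels group label per value; >= 3 levels, every group size >= 2.
#' @param posthoc_adjust `"bonferroni"` (default), `"holm"` or `"none"`.
#' @return `group_test_result` with a `posthoc` data.frame (group1, group2,
#'   z, p, p_adj) covering every pair.
#' @export
multi_group_test <- function(values, labels, posthoc_adjust = c("bonferroni", "holm", "none")) {
  posthoc_adjust <- match.arg(posthoc_adjust)
  labels <- as.character(labels)
  stopifnot(length(values) == length(labels))
  lev <- unique(labels)
  if (length(lev) < 3L) stop("multi_group_test needs >= 3 groups", call. = FALSE)
  sizes <- table(labels)
  if (any(sizes < 2L)) {
    stop(sprintf("group(s) with < 2 samples: %s",
                 paste(names(sizes)[sizes < 2L], collapse = ", ")), call. = FALSE)
  }
  if (stats::var(values) == 0) {
    kw <- list(statistic = 0, p.value = 1)
    ph <- dunn_posthoc(values, labels, adjust = posthoc_adjust)
  } else {
    kw <- stats::kruskal.test(values, factor(labels))
    ph <- dunn_posthoc(values, labels, adjust = posthoc_adjust)
  }
  structure(
    list(
      test = "Kruskal-Wallis",
      statistic = unname(kw$statistic), p = kw$p.value,
      group_sizes = stats::setNames(as.integer(sizes[lev]), lev),
      exact = FALSE, normality = NULL, posthoc = ph
    ),
    class = "group_test_result"
  )
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)%s\n",
              x$test, x$statistic, x$p,
              paste(sprintf("%s:%d", names(x$group_sizes), x$group_sizes),
                    collapse = ", "),
              if (isTRUE(x$exact)) " [exact]" else ""))
  if (!is.null(x$posthoc)) {
    cat("post hoc (Dunn):\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}
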