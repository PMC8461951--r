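#' Average-linkage (UPGMA) agglomerative clustering with deterministic ties
#'
#' Agglomerative clustering under average linkage: the distance between two
#' clusters is the mean of all pairwise distances between their members,
#' maintained by the Lance-Williams update
#' `d(ij, k) = (n_i d(i,k) + n_j d(j,k)) / (n_i + n_j)`.
#' When several cluster pairs are tied at the minimal distance, the pair with
#' the lowest first index (then lowest second index) merges first, so the
#' merge history is identical across platforms. Merge heights under UPGMA are
#' non-decreasing.
#'
#' @param d a `dist` object or a symmetric numeric distance matrix.
#' @param labels optional leaf labels; defaults to the labels of `d`.
#' @return An object of class `hclust` (merge, height, order, labels), usable
#'   with [stats::cutree()], [stats::as.dendrogram()] and [ape::as.phylo()].
#' @export
upgma <- function(d, labels = NULL) {
  if (inherits(d, "dist")) {
    labels <- labels %||% attr(d, "Labels")
    d <- as.matrix(d)
  }
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("`d` must be square", call. = FALSE)
  check_finite_matrix(d, "distance matrix")
  n <- nrow(d)
  if (n < 2L) stop("need at least two items to cluster", call. = FALSE)
  labels <- labels %||% rownames(d) %||% as.character(seq_len(n))

  # active[i]: negative leaf index or positive merge-step index, hclust coding
  active <- -seq_len(n)
  sizes <- rep(1L, n)
  alive <- rep(TRUE, n)
  D <- d
  diag(D) <- Inf
  merge <- matrix(0L, nrow = n - 1L, ncol = 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    idx <- which(alive)
    sub <- D[idx, idx, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- Inf
    m <- min(sub)
    # lowest-index tie-break: scan rows in order, first column hit within row
    hit <- which(sub == m, arr.ind = TRUE)
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    i <- idx[hit[1L, 1L]]
    j <- idx[hit[1L, 2L]]

    a <- active[i]; b <- active[j]
    # hclust convention: singletons (negative) before clusters, else ascending
    pair <- c(a, b)
    pair <- pair[order(pair >= 0L, abs(pair))]
    merge[step, ] <- pair
    height[step] <- m

    others <- idx[idx != i & idx != j]
    if (length(others) > 0L) {
      D[i, others] <- (sizes[i] * D[i, others] + sizes[j] * D[j, others]) /
        (sizes[i] + sizes[j])
      D[others, i] <- D[i, others]
    }
    sizes[i] <- sizes[i] + sizes[j]
    alive[j] <- FALSE
    active[i] <- step
  }

  hc <- list(
    merge = merge,
    height = height,
    order = upgma_leaf_order(merge),
    labels = labels,
    method = "average",
    call = match.call(),
    dist.method = "euclidean"
  )
  class(hc) <- "hclust"
  hc
}

# Leaf order by in-order traversal of the merge tree; guarantees the
# contiguity property hclust plotting requires.
upgma_leaf_order <- function(merge) {
  n <- nrow(merge) + 1L
  expand <- function(node) {
    if (node < 0L) return(-node)
    c(expand(merge[node, 1L]), expand(merge[node, 2L]))
  }
  expand(n - 1L)
}

#' Cut a dendrogram into a fixed number of clusters or at a height
#'
#' Thin, validated wrapper over [stats::cutree()] with stable labels: cluster
#' IDs are assigned in order of first appearance along the input feature
#' order, so repeated runs give identical labelings.
#'
#' @param hc an `hclust` object (e.g. from [upgma()]).
#' @param k number of clusters; mutually exclusive with `h`.
#' @param h height to cut at (clusters are the subtrees below `h`).
#' @return integer vector of cluster assignments, named by leaf label.
#' @export
cut_clusters <- function(hc, k = NULL, h = NULL) {
  stopifnot(inherits(hc, "hclust"))
  n <- length(hc$labels)
  if (is.null(k) && is.null(h)) stop("supply `k` or `h`", call. = FALSE)
  if (!is.null(k)) {
    stopifnot_scalar_count(k, "k")
    if (k > n) stop(sprintf("k = %d exceeds the number of leaves (%d)", k, n),
                    call. = FALSE)
    cl <- stats::cutree(hc, k = k)
  } else {
    cl <- stats::cutree(hc, h = h)
  }
  # relabel in order of first appearance for stability
  first <- match(unique(cl), cl)
  relab <- stats::setNames(seq_along(first), cl[first])
  out <- relab[as.character(cl)]
  names(out) <- hc$labels
  out
}

#' Choose a cluster count by maximum mean silhouette width
#'
#' Evaluates cuts of `hc` over `k_range` against the distance matrix `d` and
#' returns the `k` with the largest mean silhouette width (ties go to the
#' smallest `k`).
#'
#' @param hc an `hclust` object.
#' @param d the `dist` the tree was built from.
#' @param k_range candidate cluster counts (default 2:10, truncated to n-1).
#' @return integer, the selected `k`.
#' @export
choose_k_silhouette <- function(hc, d, k_range = 2:10) {
  n <- length(hc$labels)
  k_range <- k_range[k_range >= 2L & k_range <= n - 1L]
  if (length(k_range) == 0L) return(1L)
  width <- vapply(k_range, function(k) {
    cl <- cut_clusters(hc, k = k)
    mean(cluster::silhouette(cl, d)[, "sil_width"])
  }, numeric(1))
  k_range[which.max(width)]
}
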