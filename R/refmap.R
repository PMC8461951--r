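#' Quantile-normalize samples of an expression matrix or compendium
#'
#' Forces every sample (column) onto the common distribution given by the
#' cross-sample mean of order statistics: value at rank r becomes the mean
#' over samples of each sample's r-th smallest value. Tied values within a
#' sample all receive the mean of the mean-order-statistics of the positions
#' they jointly occupy, so the map is well defined and symmetric in ties.
#' The operation is idempotent and preserves feature/sample labels.
#'
#' @param x a numeric matrix (features x samples) or a `ref_compendium`.
#' @param ... unused.
#' @return object of the same class with normalized values.
#' @export
quantile_normalize <- function(x, ...) UseMethod("quantile_normalize")

#' @export
quantile_normalize.matrix <- function(x, ...) {
  if (ncol(x) < 2L) stop("quantile normalization needs >= 2 samples", call. = FALSE)
  check_finite_matrix(x, "expression matrix")
  n <- nrow(x)
  sorted <- apply(x, 2L, sort.int, method = "quick")
  mu <- rowMeans(sorted)
  out <- x
  for (j in seq_len(ncol(x))) {
    o <- order(x[, j])
    v <- x[o, j]
    if (anyDuplicated(v)) {
      grp <- cumsum(c(TRUE, v[-1L] != v[-n]))
      out[o, j] <- stats::ave(mu, grp)
    } else {
      out[o, j] <- mu
    }
  }
  attr(out, "scale") <- attr(x, "scale")
  out
}

#' @export
quantile_normalize.ref_compendium <- function(x, ...) {
  x$exprs <- quantile_normalize(x$exprs)
  x
}

#' Restrict a compendium to the features of a signature
#'
#' Pulls the signature's features out of the (normalized) compendium in
#' signature order and reports which features are absent from the reference
#' platform.
#'
#' @param compendium a `ref_compendium` or features x samples matrix.
#' @param features character vector of feature IDs (e.g. one direction of a
#'   signature), or a signature data.frame with a `feature_id` column.
#' @return list with `exprs` (submatrix, signature order), `missing`
#'   (character vector of absent features) and `n_missing`.
#' @export
extract_signature_submatrix <- function(compendium, features) {
  x <- if (inherits(compendium, "ref_compendium")) compendium$exprs else compendium
  if (is.data.frame(features)) features <- features$feature_id
  features <- as.character(features)
  present <- features[features %in% rownames(x)]
  missing <- setdiff(features, rownames(x))
  if (length(present) == 0L) {
    stop("no signature feature is present in the compendium: nothing to map",
         call. = FALSE)
  }
  list(exprs = x[present, , drop = FALSE], missing = missing,
       n_missing = length(missing))
}

#' Gene-to-gene Pearson correlation across reference samples
#'
#' Correlates every pair of signature features across the reference samples.
#' Features with zero variance across the compendium carry no co-expression
#' information; they are dropped from the matrix and reported.
#'
#' @param submatrix features x reference-samples matrix (signature features).
#' @return list with `R` (features x features Pearson correlation matrix) and
#'   `dropped` (zero-variance feature IDs).
#' @export
gene_gene_correlation <- function(submatrix) {
  if (ncol(submatrix) < 3L) {
    stop("gene-gene correlation needs >= 3 reference samples", call. = FALSE)
  }
  check_finite_matrix(submatrix, "signature submatrix")
  v <- apply(submatrix, 1L, stats::var)
  dropped <- rownames(submatrix)[v == 0]
  keep <- submatrix[v > 0, , drop = FALSE]
  if (nrow(keep) < 2L) stop("fewer than two features with nonzero variance", call. = FALSE)
  R <- stats::cor(t(keep), method = "pearson")
  list(R = R, dropped = dropped)
}

#' Cluster a gene-gene correlation matrix (UPGMA)
#'
#' Hierarchically clusters signature features from their correlation
#' structure. By default each feature is represented by its row of the
#' correlation matrix (its vector of correlations to all features) and
#' Euclidean distance between those rows feeds average linkage;
#' `input = "one_minus_r"` instead uses `1 - r` directly as the
#' dissimilarity.
#'
#' @param R square Pearson correlation matrix.
#' @param input `"corr_rows"` (default) or `"one_minus_r"`.
#' @return list with `hclust` (the tree, see [upgma()]), `leaf_order`
#'   (integer), and `dist` (the `dist` used).
#' @export
cluster_correlation_matrix <- function(R, input = c("corr_rows", "one_minus_r")) {
  input <- match.arg(input)
  if (!is.matrix(R) || nrow(R) != ncol(R)) stop("`R` must be square", call. = FALSE)
  check_finite_matrix(R, "correlation matrix")
  d <- if (input == "corr_rows") stats::dist(R, method = "euclidean") else stats::as.dist(1 - R)
  hc <- upgma(d, labels = rownames(R))
  list(hclust = hc, leaf_order = hc$order, dist = d)
}

#' Per-feature z-scaled, clipped display matrix
#'
#' Scales each feature (row) to mean 0 / sd 1 across the reference samples,
#' then clips to the interval \[-2, +2\] — the relative-intensity convention
#' used for ordered reference heatmaps (red = +2 above the feature mean,
#' blue = -2 below). Zero-variance rows are set to 0.
#'
#' @param submatrix features x reference-samples matrix.
#' @param clip symmetric clipping bound (default 2).
#' @return matrix of the same shape with values in `[-clip, clip]`.
#' @export
scale_display <- function(submatrix, clip = 2) {
  check_finite_matrix(submatrix, "submatrix")
  mu <- rowMeans(submatrix)
  sd <- apply(submatrix, 1L, stats::sd)
  z <- (submatrix - mu) / ifelse(sd == 0, 1, sd)
  z[sd == 0, ] <- 0
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  z
}

#' Attribute co-expression clusters to reference groups
#'
#' The attribution score of cluster c for reference group g is the mean, over
#' the cluster's features, of the mean clipped z-scored intensity over the
#' samples of g — a quantitative version of reading off, from the ordered
#' heatmap, which cell states a co-expression cluster is overrepresented in.
#'
#' @param clusters named integer vector of cluster assignments (features).
#' @param display z-scaled clipped display matrix (features x ref samples).
#' @param groups character vector of reference group labels, one per sample
#'   (column of `display`).
#' @return data.frame of class `attribution_table`: cluster, group, score,
#'   n_features, top (logical: is this the cluster's highest-scoring group);
#'   rows ordered by cluster then descending score.
#' @export
attribute_clusters <- function(clusters, display, groups) {
  stopifnot(length(groups) == ncol(display))
  feats <- intersect(names(clusters), rownames(display))
  if (length(feats) < length(clusters)) {
    clusters <- clusters[names(clusters) %in% feats]
  }
  glab <- unique(groups)
  rows <- list()
  for (cl in sort(unique(clusters))) {
    members <- names(clusters)[clusters == cl]
    if (length(members) == 0L) {
      warning(sprintf("cluster %s is empty; excluded", cl))
      next
    }
    sub <- display[members, , drop = FALSE]
    score <- vapply(glab, function(g) {
      mean(rowMeans(sub[, groups == g, drop = FALSE]))
    }, numeric(1))
    ord <- order(-score)
    rows[[length(rows) + 1L]] <- data.frame(
      cluster = cl, group = glab[ord], score = score[ord],
      n_features = length(members),
      top = seq_along(ord) == 1L,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("attribution_table", "data.frame")
  out
}

#' Map a signature onto a labeled reference compendium
#'
#' The full co-expression mapping chain: quantile-normalize the compendium,
#' extract the signature features, correlate them across the reference
#' samples, cluster the correlation matrix by UPGMA, cut into clusters
#' (explicit `k`/`h`, or maximum mean silhouette over k in 2..10 when
#' neither is given), build the clipped z-score display matrix, and attribute
#' each cluster to the reference group where its features run highest.
#' Up- and downregulated signatures are mapped in separate calls.
#'
#' @param signature character vector of feature IDs, or a signature
#'   data.frame (optionally filtered with `direction`).
#' @param compendium a `ref_compendium`.
#' @param direction if `signature` is a data.frame: `"up"`, `"down"` or
#'   `"both"` (default `"up"`).
#' @param k,h explicit cut (see [cut_clusters()]); both `NULL` selects k by
#'   silhouette.
#' @param cluster_input passed to [cluster_correlation_matrix()].
#' @param normalize quantile-normalize the compendium first (default TRUE).
#' @return A `coexpression_result`: list with `features`, `R`, `hclust`,
#'   `leaf_order`, `clusters`, `attribution`, `display`, `missing_features`,
#'   `dropped_features`, `k`.
#' @export
map_signature <- function(signature, compendium, direction = c("up", "down", "both"),
                          k = NULL, h = NULL,
                          cluster_input = c("corr_rows", "one_minus_r"),
                          normalize = TRUE) {
  direction <- match.arg(direction)
  cluster_input <- match.arg(cluster_input)
  stopifnot(inherits(compendium, "ref_compendium"))
  if (is.data.frame(signature)) {
    if (direction != "both" && "direction" %in% names(signature)) {
      signature <- signature[signature$direction == direction, , drop = FALSE]
    }
    signature <- signature$feature_id
  }
  if (length(signature) == 0L) stop("empty signature", call. = FALSE)
  if (normalize) compendium <- quantile_normalize(compendium)

  sub <- extract_signature_submatrix(compendium, signature)
  cc <- gene_gene_correlation(sub$exprs)
  cl <- cluster_correlation_matrix(cc$R, input = cluster_input)
  if (is.null(k) && is.null(h)) k <- choose_k_silhouette(cl$hclust, cl$dist)
  assign <- cut_clusters(cl$hclust, k = k, h = h)
  display <- scale_display(sub$exprs[rownames(cc$R), , drop = FALSE])
  attribution <- attribute_clusters(assign, display, compendium$samples$group)

  structure(
    list(
      features = rownames(cc$R),
      R = cc$R,
      hclust = cl$hclust,
      leaf_order = cl$hclust$order,
      clusters = assign,
      attribution = attribution,
      display = display,
      missing_features = sub$missing,
      dropped_features = cc$dropped,
      k = length(unique(assign)),
      groups = compendium$samples$group
    ),
    class = "coexpression_result"
  )
}

#' @export
print.coexpression_result <- function(x, ...) {
  cat(sprintf("coexpression_result: %d features, %d clusters\n",
              length(x$features), x$k))
  top <- x$attribution[x$attribution$top, , drop = FALSE]
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  cluster %d (%d features) -> %s (score %.3f)\n",
                top$cluster[i], top$n_features[i], top$group[i], top$score[i]))
  }
  if (length(x$missing_features) > 0L) {
    cat(sprintf("  %d signature feature(s) absent from the compendium\n",
                length(x$missing_features)))
  }
  invisible(x)
}

#' Export a dendrogram as Newick text
#' @param hc an `hclust` object.
#' @param path output file.
#' @export
write_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Render the ordered relative-intensity heatmap
#'
#' Draws the clipped z-score display matrix with rows in dendrogram leaf
#' order and columns in the declared reference-sample order, on a fixed
#' blue-white-red scale over \[-2, +2\], and exports the ordered numeric
#' matrix alongside so the figure can be regenerated bit-exactly.
#'
#' @param result a `coexpression_result`.
#' @param png_path output PNG path (`NULL` to skip rendering).
#' @param matrix_path output TSV path for the ordered matrix (`NULL` to skip).
#' @param sample_order optional integer/character ordering of the reference
#'   samples; default keeps the compendium's declared family order.
#' @param width,height device size in pixels.
#' @return invisibly, the ordered display matrix.
#' @export
render_ordered_heatmap <- function(result, png_path = NULL, matrix_path = NULL,
                                   sample_order = NULL, width = 900, height = 700) {
  stopifnot(inherits(result, "coexpression_result"))
  m <- result$display[result$leaf_order, , drop = FALSE]
  if (!is.null(sample_order)) m <- m[, sample_order, drop = FALSE]
  if (!is.null(matrix_path)) {
    write_expression_matrix(m, matrix_path)
  }
  if (!is.null(png_path)) {
    pal <- grDevices::colorRampPalette(c("#2166AC", "#FFFFFF", "#B2182B"))(256)
    grDevices::png(png_path, width = width, height = height)
    on.exit(grDevices::dev.off())
    graphics::par(mar = c(6, 1, 2, 6))
    # image() draws rows bottom-up; flip so the first leaf is on top
    graphics::image(
      x = seq_len(ncol(m)), y = seq_len(nrow(m)),
      z = t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
      zlim = c(-2, 2), col = pal, axes = FALSE, xlab = "", ylab = "",
      main = "signature co-expression in reference compendium"
    )
    graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2,
                   cex.axis = 0.6, tick = FALSE)
    graphics::axis(4, at = seq_len(nrow(m)), labels = rev(rownames(m)), las = 2,
                   cex.axis = 0.4, tick = FALSE)
  }
  invisible(m)
}
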