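#' Score two-group differential expression and build a signature
#'
#' Computes, for every feature, a two-sided test between the two groups
#' (Welch t by default, or a Wilcoxon rank-sum), the multiplicity-adjusted
#' p-value (Benjamini-Hochberg by default; `mt_procedure = "none"` keeps the
#' raw p, matching a raw p < 0.05 cut-off), and the linear-scale fold change
#' of group means (log2 input is exponentiated before taking the ratio).
#' Features passing `p_adj < alpha` form the signature, split into up- and
#' downregulated lists by the sign of the log2 fold change.
#'
#' A feature with zero variance in both groups is uninformative: its
#' statistic is defined as 0 with p = 1 rather than an error.
#'
#' @param x features x samples numeric matrix.
#' @param labels character/factor vector over columns; exactly two levels.
#' @param case,control the two labels to contrast (fold change is
#'   case over control). Default: first two unique labels in order.
#' @param method `"welch_t"` or `"rank_sum"`.
#' @param alpha significance threshold on the adjusted p (default 0.05).
#' @param mt_procedure `"BH"` (default) or `"none"`.
#' @param scale `"log2"` (default) or `"linear"`: how values map to fold
#'   changes. Defaults to the matrix's `"scale"` attribute when present.
#' @param batch optional vector over columns; when given, each feature is
#'   centered within batch before scoring (a covariate-adjustment hook for
#'   cohorts pooled across sequencing runs).
#' @return list of class `de_result`: `table` (per-feature feature_id,
#'   statistic, p, p_adj, fold_change, direction), `signature` (the subset
#'   with p_adj < alpha, class `sigmap_signature`), `up`, `down` (feature
#'   IDs), and the call parameters.
#' @export
score_two_group <- function(x, labels, case = NULL, control = NULL,
                            method = c("welch_t", "rank_sum"),
                            alpha = 0.05, mt_procedure = c("BH", "none"),
                            scale = NULL, batch = NULL) {
  method <- match.arg(method)
  mt_procedure <- match.arg(mt_procedure)
  stopifnot(is.matrix(x), length(labels) == ncol(x))
  scale <- scale %||% attr(x, "scale") %||% "log2"
  scale <- match.arg(scale, c("log2", "linear", "count"))
  labels <- as.character(labels)
  lev <- unique(labels)
  case <- case %||% lev[1L]
  control <- control %||% lev[2L]
  if (!all(c(case, control) %in% lev)) {
    stop("`case`/`control` must be levels of `labels`", call. = FALSE)
  }
  g1 <- which(labels == case)
  g2 <- which(labels == control)
  if (length(g1) < 2L || length(g2) < 2L) {
    stop("need >= 2 samples per group", call. = FALSE)
  }
  check_finite_matrix(x, "expression matrix")
  if (!is.null(batch)) {
    stopifnot(length(batch) == ncol(x))
    for (b in unique(batch)) {
      cols <- which(batch == b)
      x[, cols] <- x[, cols, drop = FALSE] - rowMeans(x[, cols, drop = FALSE])
    }
  }

  x1 <- x[, g1, drop = FALSE]
  x2 <- x[, g2, drop = FALSE]
  n1 <- length(g1); n2 <- length(g2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  if (method == "welch_t") {
    v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
    v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
    se2 <- v1 / n1 + v2 / n2
    stat <- ifelse(se2 == 0, 0, (m1 - m2) / sqrt(se2))
    df <- ifelse(se2 == 0, 1,
                 se2^2 / (v1^2 / (n1^2 * (n1 - 1L)) + v2^2 / (n2^2 * (n2 - 1L))))
    p <- ifelse(se2 == 0, 1, 2 * stats::pt(-abs(stat), df = df))
  } else {
    stat <- numeric(nrow(x))
    p <- numeric(nrow(x))
    for (i in seq_len(nrow(x))) {
      if (stats::var(x1[i, ]) == 0 && stats::var(x2[i, ]) == 0 &&
          m1[i] == m2[i]) {
        stat[i] <- 0; p[i] <- 1
      } else {
        wt <- suppressWarnings(stats::wilcox.test(x1[i, ], x2[i, ], exact = FALSE,
                                                  correct = TRUE))
        stat[i] <- unname(wt$statistic)
        p[i] <- wt$p.value
      }
    }
  }
  p_adj <- if (mt_procedure == "BH") stats::p.adjust(p, method = "BH") else p
  fc <- if (scale == "log2") 2^(m1 - m2) else {
    ifelse(m2 == 0, NA_real_, m1 / m2)
  }
  direction <- ifelse(fc >= 1, "up", "down")

  table <- data.frame(
    feature_id = rownames(x) %||% as.character(seq_len(nrow(x))),
    direction = direction,
    score = stat,
    p = p,
    p_adj = p_adj,
    fold_change = fc,
    stringsAsFactors = FALSE
  )
  sig <- table[table$p_adj < alpha, , drop = FALSE]
  rownames(sig) <- NULL
  class(sig) <- c("sigmap_signature", "data.frame")
  structure(
    list(
      table = table,
      signature = sig,
      up = sig$feature_id[sig$direction == "up"],
      down = sig$feature_id[sig$direction == "down"],
      contrast = sprintf("%s_vs_%s", case, control),
      method = method, alpha = alpha, mt_procedure = mt_procedure
    ),
    class = "de_result"
  )
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("de_result [%s, %s]: %d features, %d significant (%d up, %d down) at p_adj < %g\n",
              x$contrast, x$method, nrow(x$table), nrow(x$signature),
              length(x$up), length(x$down), x$alpha))
  invisible(x)
}

#' Pairwise case/control concordance score
#'
#' For each feature, the fraction of all case x control sample pairs in which
#' the case value exceeds the control value (ties count as half a pair),
#' mapped to a signed score in \[-100, 100\] as `200 * (fraction - 0.5)`.
#' A score of 100 means every case exceeds every control; 0 means no
#' concordance either way. The score depends only on ranks, so it is
#' invariant under any strictly monotone transform of the data. Features
#' with `|score|` above `cutoff` form the signature.
#'
#' @param x features x samples matrix.
#' @param labels vector over columns.
#' @param case,control labels of the two groups (default first two levels).
#' @param cutoff absolute score cut-off for signature membership
#'   (default 100, i.e. full concordance).
#' @return data.frame: feature_id, concordant_fraction, score, in_signature.
#' @export
score_pairwise_concordance <- function(x, labels, case = NULL, control = NULL,
                                       cutoff = 100) {
  stopifnot(is.matrix(x), length(labels) == ncol(x))
  labels <- as.character(labels)
  lev <- unique(labels)
  case <- case %||% lev[1L]
  control <- control %||% lev[2L]
  g1 <- which(labels == case)
  g2 <- which(labels == control)
  if (length(g1) < 1L || length(g2) < 1L) {
    stop("need >= 1 case and >= 1 control", call. = FALSE)
  }
  frac <- vapply(seq_len(nrow(x)), function(i) {
    diff <- outer(x[i, g1], x[i, g2], `-`)
    (sum(diff > 0) + 0.5 * sum(diff == 0)) / length(diff)
  }, numeric(1))
  score <- 200 * (frac - 0.5)
  data.frame(
    feature_id = rownames(x) %||% as.character(seq_len(nrow(x))),
    concordant_fraction = frac,
    score = score,
    in_signature = abs(score) >= cutoff,
    stringsAsFactors = FALSE
  )
}
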