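#' Hypergeometric gene-set over-representation
#'
#' Tests each gene set for overlap with a query gene list against a declared
#' universe. With universe size N, set size K (after intersecting the set
#' with the universe), query size n and overlap k, the p-value is the upper
#' tail `P[X >= k]` for X ~ Hypergeometric(N, K, n). Benjamini-Hochberg
#' adjustment is applied across all sets in the collection; sets are ranked
#' by p.
#'
#' @param query character vector of gene symbols; must be contained in
#'   `universe`.
#' @param collection a `gene_set_collection` (see [read_gmt()]) or named list
#'   of character vectors.
#' @param universe character vector of all assayable genes (e.g. all matrix
#'   rows after annotation).
#' @return data.frame of class `enrichment_result`, one row per set:
#'   set, N, K, n, k, p, p_adj, overlap (semicolon-joined members), ordered
#'   by p.
#' @export
overrepresentation <- function(query, collection, universe) {
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  if (length(query) == 0L) stop("empty query", call. = FALSE)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    stop(sprintf("query gene(s) outside the universe: %s",
                 paste(utils::head(outside, 10L), collapse = ", ")), call. = FALSE)
  }
  if (length(collection) == 0L) stop("empty gene-set collection", call. = FALSE)
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(unique(collection[[nm]]), universe)
    K <- length(set)
    ov <- intersect(query, set)
    k <- length(ov)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, N = N, K = K, n = n, k = k, p = p,
               overlap = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set), c("set", "N", "K", "n", "k", "p", "p_adj", "overlap")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Over-representation per co-expression cluster
#'
#' Translates each cluster's probe-sets to gene symbols through the
#' annotation map (collapsing duplicates, so a gene hit by several
#' probe-sets counts once), then runs [overrepresentation()] per cluster.
#' Clusters with fewer than `min_size` mapped genes are skipped with a
#' warning; if none qualifies, that is an error.
#'
#' @param clusters named integer vector of cluster assignments (probe-sets).
#' @param annotation an `annotation_map`.
#' @param collection gene-set collection.
#' @param universe gene universe; default all genes in `annotation`.
#' @param min_size minimum mapped genes per tested cluster (default 5).
#' @return named list (`cluster_<id>`) of `enrichment_result` tables.
#' @export
enrich_clusters <- function(clusters, annotation, collection, universe = NULL,
                            min_size = 5L) {
  stopifnot(inherits(annotation, "annotation_map"))
  universe <- universe %||% unique(annotation$gene_symbol)
  out <- list()
  for (cl in sort(unique(clusters))) {
    probes <- names(clusters)[clusters == cl]
    genes <- unique(annotation$gene_symbol[annotation$probe_set_id %in% probes])
    genes <- intersect(genes, universe)
    if (length(genes) < min_size) {
      warning(sprintf("cluster %s: %d mapped gene(s) < min_size %d; skipped",
                      cl, length(genes), min_size))
      next
    }
    out[[sprintf("cluster_%s", cl)]] <- overrepresentation(genes, collection, universe)
  }
  if (length(out) == 0L) {
    stop("no cluster meets the minimum size for enrichment", call. = FALSE)
  }
  out
}
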