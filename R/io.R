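#' Read a tab-delimited expression matrix
#'
#' Expects features in rows and samples in columns, with a header row of
#' sample IDs and the first column holding feature IDs. Parsing is strict:
#' ragged rows and non-numeric cells are rejected with the offending line
#' number, never silently coerced.
#'
#' @param path file path.
#' @param scale declared scale of the values, `"log2"` or `"count"`; recorded
#'   as the `"scale"` attribute of the returned matrix.
#' @param duplicate_policy what to do with duplicated feature IDs: `"error"`
#'   (default), `"first"` (keep first occurrence) or `"mean"` (average rows).
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
read_expression_matrix <- function(path, scale = c("log2", "count"),
                                   duplicate_policy = c("error", "first", "mean")) {
  scale <- match.arg(scale)
  duplicate_policy <- match.arg(duplicate_policy)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("expression matrix needs a header row and >= 1 data row",
                               call. = FALSE)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  # A leading ID column header may be present or empty; samples are the rest.
  sample_ids <- header[-1L]
  n_col <- length(header)
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  widths <- lengths(rows)
  if (any(widths != n_col)) {
    bad <- which(widths != n_col)[1L]
    stop(sprintf("line %d: expected %d fields, found %d", bad + 1L, n_col, widths[bad]),
         call. = FALSE)
  }
  ids <- vapply(rows, `[[`, character(1), 1L)
  cells <- lapply(rows, function(r) r[-1L])
  vals <- lapply(cells, function(v) suppressWarnings(as.numeric(v)))
  for (i in seq_along(vals)) {
    bad <- which(is.na(vals[[i]]) & !(toupper(cells[[i]]) %in% c("NA", "NAN")))
    if (length(bad) > 0L) {
      stop(sprintf("line %d: non-numeric cell '%s' (column %d)",
                   i + 1L, cells[[i]][bad[1L]], bad[1L] + 1L), call. = FALSE)
    }
  }
  x <- do.call(rbind, vals)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    if (duplicate_policy == "error") {
      stop(sprintf("duplicated feature ID(s): %s", paste(utils::head(dup, 10L),
                                                         collapse = ", ")), call. = FALSE)
    } else if (duplicate_policy == "first") {
      keep <- !duplicated(ids)
      x <- x[keep, , drop = FALSE]
      ids <- ids[keep]
    } else {
      x <- rowsum(x, group = ids, reorder = FALSE) / as.vector(table(ids)[unique(ids)])
      ids <- rownames(x)
    }
  }
  dimnames(x) <- list(ids, sample_ids)
  message(sprintf("read_expression_matrix: %d features x %d samples from %s",
                  nrow(x), ncol(x), path))
  attr(x, "scale") <- scale
  x
}

#' Write an expression matrix as tab-delimited text
#'
#' Features in rows (first column `feature_id`), samples in columns. Values
#' are written with full double precision so write/read round trips are
#' lossless.
#'
#' @param x numeric matrix with dimnames.
#' @param path output path.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("feature_id", colnames(x)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], sprintf("%.17g", x[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read sample metadata (sample_id, group[, dataset]) from TSV
#' @param path file path to a TSV with a header.
#' @return data.frame.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  meta <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "group")
  if (!all(need %in% names(meta))) {
    stop("sample metadata must have columns sample_id and group", call. = FALSE)
  }
  if (anyDuplicated(meta$sample_id)) stop("duplicated sample_id in metadata", call. = FALSE)
  meta
}

#' @rdname read_sample_metadata
#' @param meta data.frame to write.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard tab-delimited GMT: one set per line as
#' `name<TAB>description<TAB>member1<TAB>member2...`. Lines with fewer than
#' three fields, empty member lists and duplicated set names are rejected
#' with the offending line number.
#'
#' @param path GMT file path.
#' @return A `gene_set_collection`: named list of character vectors with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop(sprintf("line %d: GMT line needs >= 3 fields", i), call. = FALSE)
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (length(members) == 0L) stop(sprintf("line %d: empty member list", i), call. = FALSE)
    if (f[1L] %in% names(sets)) {
      stop(sprintf("line %d: duplicated set name '%s'", i, f[1L]), call. = FALSE)
    }
    sets[[f[1L]]] <- unique(members)
    desc[f[1L]] <- f[2L]
  }
  structure(sets, descriptions = desc, class = "gene_set_collection")
}

#' @rdname read_gmt
#' @param collection named list of character vectors (set members).
#' @param descriptions optional named character vector of set descriptions.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  descriptions <- descriptions %||% attr(collection, "descriptions") %||%
    stats::setNames(rep("na", length(collection)), names(collection))
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, descriptions[[nm]] %||% "na", collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a probe-set/gene annotation table
#'
#' Two-column TSV (`probe_set_id`, `gene_symbol`); the mapping may be
#' many-to-many. Empty IDs are rejected; matching elsewhere in the package is
#' exact-string and case-preserving.
#'
#' @param path TSV path with header.
#' @return data.frame of class `annotation_map`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ann <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("probe_set_id", "gene_symbol") %in% names(ann))) {
    stop("annotation must have columns probe_set_id and gene_symbol", call. = FALSE)
  }
  annotation_map(ann$probe_set_id, ann$gene_symbol)
}

#' Construct an annotation map from paired vectors
#' @param probe_set_id,gene_symbol equal-length character vectors.
#' @return data.frame of class `annotation_map`.
#' @export
annotation_map <- function(probe_set_id, gene_symbol) {
  probe_set_id <- as.character(probe_set_id)
  gene_symbol <- as.character(gene_symbol)
  if (length(probe_set_id) != length(gene_symbol)) {
    stop("probe_set_id and gene_symbol must have equal length", call. = FALSE)
  }
  if (any(!nzchar(probe_set_id)) || any(!nzchar(gene_symbol)) ||
      anyNA(probe_set_id) || anyNA(gene_symbol)) {
    stop("annotation IDs must be non-empty", call. = FALSE)
  }
  ann <- unique(data.frame(probe_set_id = probe_set_id, gene_symbol = gene_symbol,
                           stringsAsFactors = FALSE))
  class(ann) <- c("annotation_map", "data.frame")
  ann
}

#' Map gene symbols to probe-sets through an annotation table
#'
#' Expansion is one-to-many: every probe-set of every mapped gene is
#' returned. Coverage is the fraction of input genes with at least one
#' probe-set (the quantity that bounds how much of an RNA-seq signature a
#' microarray compendium can represent).
#'
#' @param genes character vector of gene symbols.
#' @param annotation an `annotation_map`.
#' @param case_fold if `TRUE`, match case-insensitively (default exact).
#' @return list with `probe_sets` (character), `coverage` (fraction mapped,
#'   `NA` for empty input) and `unmapped` (character).
#' @export
map_genes_to_probesets <- function(genes, annotation, case_fold = FALSE) {
  stopifnot(inherits(annotation, "annotation_map"))
  genes <- as.character(genes)
  if (length(genes) == 0L) {
    return(list(probe_sets = character(0), coverage = NA_real_, unmapped = character(0)))
  }
  key <- if (case_fold) toupper(annotation$gene_symbol) else annotation$gene_symbol
  qry <- if (case_fold) toupper(genes) else genes
  hit <- key %in% qry
  mapped_genes <- genes[qry %in% key]
  list(
    probe_sets = unique(annotation$probe_set_id[hit]),
    coverage = length(unique(mapped_genes)) / length(unique(genes)),
    unmapped = setdiff(genes, mapped_genes)
  )
}

#' Read/write a differential-expression signature table
#'
#' Signature TSVs have columns `feature_id`, `direction` (up/down), `score`,
#' `p_adj`, `fold_change`.
#'
#' @param path TSV path.
#' @return data.frame of class `sigmap_signature`.
#' @export
read_signature <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  sig <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("feature_id", "direction", "score", "p_adj", "fold_change")
  if (!all(need %in% names(sig))) {
    stop(sprintf("signature TSV must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(sig$feature_id)) stop("duplicated feature_id in signature", call. = FALSE)
  class(sig) <- c("sigmap_signature", "data.frame")
  sig
}

#' @rdname read_signature
#' @param signature signature data.frame to write.
#' @export
write_signature <- function(signature, path) {
  out <- as.data.frame(signature)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], format_num)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
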