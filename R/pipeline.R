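#' Load and validate a pipeline configuration
#'
#' The configuration is a single YAML file naming the inputs (expression
#' matrix, sample metadata, reference compendium + metadata, optional GMT,
#' annotation and marker tables), the contrasts to run (metadata column plus
#' case/control level sets), the DE settings, the refmap cut rule, and the
#' output directory. All referenced paths and contrast levels are validated
#' before any computation.
#'
#' @param path YAML file path, or a pre-built list with the same fields.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(path) {
  cfg <- if (is.list(path)) path else {
    if (!file.exists(path)) stop(sprintf("config not found: %s", path), call. = FALSE)
    yaml::read_yaml(path)
  }
  need <- c("matrix", "metadata", "compendium", "compendium_metadata",
            "contrasts", "output_dir")
  miss <- setdiff(need, names(cfg))
  if (length(miss) > 0L) {
    stop(sprintf("config is missing field(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  for (f in c("matrix", "metadata", "compendium", "compendium_metadata",
              "gmt", "annotation", "markers")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stop(sprintf("config field '%s': file not found: %s", f, cfg[[f]]), call. = FALSE)
    }
  }
  meta <- read_sample_metadata(cfg$metadata)
  for (i in seq_along(cfg$contrasts)) {
    ct <- cfg$contrasts[[i]]
    if (is.null(ct$name) || is.null(ct$column) || is.null(ct$case) || is.null(ct$control)) {
      stop(sprintf("contrast %d needs fields name, column, case, control", i), call. = FALSE)
    }
    if (!ct$column %in% names(meta)) {
      stop(sprintf("contrast '%s': column '%s' not in metadata", ct$name, ct$column),
           call. = FALSE)
    }
    lev <- unique(meta[[ct$column]])
    bad <- setdiff(c(unlist(ct$case), unlist(ct$control)), lev)
    if (length(bad) > 0L) {
      stop(sprintf("contrast '%s': unknown level(s) in column '%s': %s",
                   ct$name, ct$column, paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  cfg$de <- utils::modifyList(
    list(method = "welch_t", alpha = 0.05, mt = "BH"), cfg$de %||% list())
  cfg$refmap <- utils::modifyList(
    list(k = NULL, cluster_input = "corr_rows"), cfg$refmap %||% list())
  cfg$seed <- cfg$seed %||% 1L
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

write_result_tsv <- function(df, path) {
  out <- as.data.frame(df)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], format_num)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full signature-to-reference mapping pipeline
#'
#' For each configured contrast: scores two-group differential expression,
#' writes the up/down signature tables, maps each direction onto the
#' reference compendium (quantile normalization, correlation, UPGMA
#' clustering, attribution, ordered display matrix + heatmap), runs
#' per-cluster gene-set over-representation when a GMT and annotation are
#' configured, and runs the serum-marker group test when a marker table is
#' configured. A manifest (package version, seed, config hash, per-stage
#' feature counts) is written as JSON. All numeric outputs are written with
#' deterministic formatting, so re-running an identical config reproduces
#' byte-identical tables.
#'
#' @param config a `pipeline_config` or path to the YAML.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message(sprintf(...))

  x <- suppressMessages(read_expression_matrix(cfg$matrix))
  meta <- read_sample_metadata(cfg$metadata)
  if (!all(colnames(x) %in% meta$sample_id)) {
    stop("stage read_inputs: matrix columns missing from metadata", call. = FALSE)
  }
  meta <- meta[match(colnames(x), meta$sample_id), , drop = FALSE]
  comp <- structure(
    list(exprs = suppressMessages(read_expression_matrix(cfg$compendium)),
         samples = read_sample_metadata(cfg$compendium_metadata)),
    class = "ref_compendium"
  )
  comp$samples <- comp$samples[match(colnames(comp$exprs), comp$samples$sample_id), ,
                               drop = FALSE]
  comp_norm <- quantile_normalize(comp)
  ann <- if (!is.null(cfg$annotation)) read_annotation(cfg$annotation) else NULL
  gmt <- if (!is.null(cfg$gmt)) read_gmt(cfg$gmt) else NULL

  manifest <- list(
    package = "sigmap",
    version = as.character(utils::packageVersion("sigmap")),
    seed = cfg$seed,
    config_hash = if (is.character(cfg$source_path %||% NULL))
      unname(tools::md5sum(cfg$source_path)) else NA_character_,
    de = cfg$de,
    contrasts = list()
  )

  for (ct in cfg$contrasts) {
    log_msg("contrast '%s': %s vs %s", ct$name, paste(unlist(ct$case), collapse = "+"),
            paste(unlist(ct$control), collapse = "+"))
    lab <- ifelse(meta[[ct$column]] %in% unlist(ct$case), "case",
                  ifelse(meta[[ct$column]] %in% unlist(ct$control), "control", NA))
    keep <- !is.na(lab)
    de <- score_two_group(
      x[, keep, drop = FALSE], lab[keep], case = "case", control = "control",
      method = cfg$de$method, alpha = cfg$de$alpha,
      mt_procedure = if (identical(cfg$de$mt, "none")) "none" else "BH"
    )
    log_msg("  %d features scored, %d significant (%d up / %d down)",
            nrow(de$table), nrow(de$signature), length(de$up), length(de$down))
    cdir <- file.path(cfg$output_dir, ct$name)
    dir.create(cdir, showWarnings = FALSE, recursive = TRUE)
    write_result_tsv(de$table, file.path(cdir, "de_table.tsv"))
    write_signature(de$signature, file.path(cdir, "signature.tsv"))

    cinfo <- list(name = ct$name, n_significant = nrow(de$signature),
                  n_up = length(de$up), n_down = length(de$down), refmap = list())
    for (dir_lab in c("up", "down")) {
      feats <- de[[dir_lab]]
      feats <- feats[feats %in% rownames(comp_norm$exprs)]
      if (length(feats) < 3L) {
        log_msg("  [%s] %d mappable feature(s) < 3; refmap skipped", dir_lab, length(feats))
        next
      }
      res <- map_signature(feats, comp_norm, k = cfg$refmap$k,
                           cluster_input = cfg$refmap$cluster_input,
                           normalize = FALSE)
      log_msg("  [%s] mapped %d features into %d clusters", dir_lab,
              length(res$features), res$k)
      stem <- file.path(cdir, dir_lab)
      write_expression_matrix(res$R, paste0(stem, "_correlation.tsv"))
      write_newick(res$hclust, paste0(stem, "_dendrogram.nwk"))
      write_result_tsv(
        data.frame(feature_id = names(res$clusters), cluster = unname(res$clusters),
                   stringsAsFactors = FALSE),
        paste0(stem, "_clusters.tsv")
      )
      write_result_tsv(res$attribution, paste0(stem, "_attribution.tsv"))
      render_ordered_heatmap(res, png_path = paste0(stem, "_heatmap.png"),
                             matrix_path = paste0(stem, "_display.tsv"))
      cinfo$refmap[[dir_lab]] <- list(n_mapped = length(res$features), k = res$k)

      if (!is.null(ann) && !is.null(gmt)) {
        enr <- tryCatch(
          enrich_clusters(res$clusters, ann, gmt),
          error = function(e) NULL
        )
        if (!is.null(enr)) {
          enr_df <- do.call(rbind, lapply(names(enr), function(nm) {
            cbind(cluster = nm, enr[[nm]], stringsAsFactors = FALSE)
          }))
          write_result_tsv(enr_df, paste0(stem, "_enrichment.tsv"))
        }
      }
    }
    manifest$contrasts[[ct$name]] <- cinfo
  }

  if (!is.null(cfg$markers)) {
    mk <- utils::read.delim(cfg$markers, stringsAsFactors = FALSE)
    stats_rows <- lapply(unique(mk$analyte), function(a) {
      sub <- mk[mk$analyte == a, , drop = FALSE]
      ng <- length(unique(sub$group))
      gt <- if (ng == 2L) two_group_test(sub$value, sub$group)
            else multi_group_test(sub$value, sub$group)
      data.frame(analyte = a, test = gt$test, statistic = gt$statistic, p = gt$p,
                 stringsAsFactors = FALSE)
    })
    write_result_tsv(do.call(rbind, stats_rows),
                     file.path(cfg$output_dir, "marker_tests.tsv"))
  }

  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Write a complete synthetic demo dataset and its pipeline config
#'
#' Generates, under `dir`: a 70-sample reference compendium over four
#' myeloid reference families with four planted marker blocks; a 25-case vs
#' 10-control expression matrix whose planted up-signature is drawn from two
#' of the compendium blocks and whose down-signature from a third (mean fold
#' change 1.20); a serum-marker table with a planted case/control shift; a
#' probe-set/gene annotation; a small GMT whose first sets are the planted
#' block gene lists plus decoys; the ground-truth tables; and a ready-to-run
#' `run.yaml`.
#'
#' @param dir target directory; must be empty unless `force = TRUE`.
#' @param seed integer seed driving every generated artifact.
#' @param force overwrite a nonempty directory.
#' @return invisibly, the path of the written config.
#' @export
make_demo <- function(dir, seed = 1L, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !force) {
    stop(sprintf("directory '%s' is not empty (use force = TRUE)", dir), call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)

  cspec <- default_compendium_spec(seed = seed)
  comp <- generate_compendium(cspec)
  write_expression_matrix(comp$exprs, file.path(dir, "compendium.tsv"))
  write_sample_metadata(comp$samples, file.path(dir, "compendium_meta.tsv"))
  write_result_tsv(comp$truth, file.path(dir, "compendium_truth.tsv"))

  # planted signature: up-features from blocks 1 (BM) and 4 (stimulated
  # monocytes), down-features from block 2 (blood subsets / DC-like)
  blocks <- cspec$blocks
  up_feats <- c(blocks[[1L]]$features, blocks[[4L]]$features)
  down_feats <- blocks[[2L]]$features
  ccspec <- case_control_spec(
    n_cases = 25L, n_controls = 10L, n_features = cspec$n_features,
    signature_features = c(up_feats, down_feats),
    direction = rep(c("up", "down"), c(length(up_feats), length(down_feats))),
    mean_fc = 1.20, fc_dispersion = 0, noise_sd = 0.15, seed = seed + 1L
  )
  cc <- generate_case_control(ccspec)
  write_expression_matrix(cc$exprs, file.path(dir, "cohort.tsv"))
  write_sample_metadata(cc$samples, file.path(dir, "cohort_meta.tsv"))
  write_result_tsv(cc$truth, file.path(dir, "cohort_truth.tsv"))

  markers <- generate_serum_markers(
    group_means = c(case = 18, control = 9),
    group_sds = c(case = 0.35, control = 0.35),
    group_ns = c(case = 29L, control = 11L),
    distribution = "lognormal", analyte = "LBP_like", seed = seed + 2L
  )
  write_result_tsv(markers, file.path(dir, "markers.tsv"))

  feature_ids <- rownames(comp$exprs)
  ann <- annotation_map(feature_ids, sub("^F", "GENE", feature_ids))
  write_result_tsv(as.data.frame(ann), file.path(dir, "annotation.tsv"))

  block_sets <- lapply(seq_along(blocks), function(i) {
    sub("^F", "GENE", feature_ids[blocks[[i]]$features])
  })
  names(block_sets) <- sprintf("BLOCK%d_MARKERS", seq_along(blocks))
  decoys <- with_rng(seed + 3L, {
    lapply(1:4, function(i) sample(sub("^F", "GENE", feature_ids), 30L))
  })
  names(decoys) <- sprintf("DECOY_SET_%d", 1:4)
  write_gmt(c(block_sets, decoys), file.path(dir, "sets.gmt"))

  cfg <- list(
    matrix = file.path(dir, "cohort.tsv"),
    metadata = file.path(dir, "cohort_meta.tsv"),
    compendium = file.path(dir, "compendium.tsv"),
    compendium_metadata = file.path(dir, "compendium_meta.tsv"),
    gmt = file.path(dir, "sets.gmt"),
    annotation = file.path(dir, "annotation.tsv"),
    markers = file.path(dir, "markers.tsv"),
    contrasts = list(list(name = "case_vs_control", column = "group",
                          case = "case", control = "control")),
    de = list(method = "welch_t", alpha = 0.05, mt = "BH"),
    refmap = list(cluster_input = "corr_rows"),
    output_dir = file.path(dir, "results"),
    seed = seed
  )
  cfg_path <- file.path(dir, "run.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(cfg_path)
}
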