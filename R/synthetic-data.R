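#' Specify a planted marker block for a synthetic reference compendium
#'
#' A block is a set of features elevated (by `effect_log2` on the log2 scale)
#' in a subset of the compendium's reference groups, emulating cell-state
#' marker genes that light up in, say, late granulopoiesis or dendritic cells.
#'
#' @param features integer vector of feature indices belonging to the block.
#' @param high_groups character vector of group labels in which the block is
#'   elevated; must be a non-empty proper subset of the compendium's groups.
#' @param effect_log2 elevation above baseline in log2 units; must be > 0.
#' @return A `block_spec` list.
#' @export
block_spec <- function(features, high_groups, effect_log2) {
  features <- as.integer(features)
  if (length(features) == 0L || anyNA(features) || any(features < 1L)) {
    stop("`features` must be positive integer indices", call. = FALSE)
  }
  if (anyDuplicated(features)) {
    stop("`features` within a block must be unique", call. = FALSE)
  }
  if (length(high_groups) == 0L) {
    stop("`high_groups` must be non-empty", call. = FALSE)
  }
  if (!is.numeric(effect_log2) || length(effect_log2) != 1L || effect_log2 <= 0) {
    stop("`effect_log2` must be a single value > 0", call. = FALSE)
  }
  structure(
    list(
      features = sort(features),
      high_groups = as.character(high_groups),
      effect_log2 = as.numeric(effect_log2)
    ),
    class = "block_spec"
  )
}

#' Specify a synthetic reference compendium
#'
#' @param groups named integer vector: number of samples per reference group
#'   (e.g. `c(BM_myelopoiesis = 34, blood_subsets = 15)`).
#' @param n_features number of features in the compendium.
#' @param blocks list of [block_spec()] objects; feature index sets must be
#'   pairwise disjoint.
#' @param noise_sd standard deviation of additive Gaussian noise, log2 scale.
#' @param baseline_mean log2 baseline expression of every feature.
#' @param seed integer RNG seed.
#' @return A `compendium_spec` list, validated.
#' @export
compendium_spec <- function(groups, n_features, blocks = list(),
                            noise_sd = 0.25, baseline_mean = 7, seed = 1L) {
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("`groups` must be a named vector of per-group sample counts", call. = FALSE)
  }
  if (anyDuplicated(names(groups))) stop("group labels must be unique", call. = FALSE)
  if (any(groups < 1L)) stop("every group needs n_samples >= 1", call. = FALSE)
  stopifnot_scalar_count(n_features, "n_features")
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)

  labels <- names(groups)
  all_feat <- integer(0)
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    if (!inherits(b, "block_spec")) stop("`blocks` must be block_spec objects", call. = FALSE)
    if (!all(b$high_groups %in% labels)) {
      stop(sprintf("block %d: unknown group(s) %s", i,
                   paste(setdiff(b$high_groups, labels), collapse = ", ")), call. = FALSE)
    }
    if (length(unique(b$high_groups)) >= length(labels)) {
      stop(sprintf("block %d: high_groups must be a proper subset of groups", i), call. = FALSE)
    }
    clash <- intersect(all_feat, b$features)
    if (length(clash) > 0L) {
      stop(sprintf("blocks overlap at feature indices: %s",
                   paste(utils::head(clash, 20L), collapse = ", ")), call. = FALSE)
    }
    if (any(b$features > n_features)) {
      stop(sprintf("block %d references features beyond n_features", i), call. = FALSE)
    }
    all_feat <- c(all_feat, b$features)
  }
  if (length(all_feat) > n_features) {
    stop("n_features must be >= total number of block features", call. = FALSE)
  }
  structure(
    list(groups = groups, n_features = as.integer(n_features), blocks = blocks,
         noise_sd = as.numeric(noise_sd), baseline_mean = as.numeric(baseline_mean),
         seed = as.integer(seed)),
    class = "compendium_spec"
  )
}

#' Default compendium template: four myeloid reference families
#'
#' Mirrors the structure of a 70-sample myeloid reference compendium: a bone
#' marrow myelopoiesis series (34 samples), blood cell subsets including DCs,
#' PMNs and monocyte subsets (15), G-CSF-treated blood leukocytes (6), and
#' in vitro monocytes across five stimulation conditions (15). One marker
#' block of 40 features is planted per family.
#'
#' @param n_features total features (default 400).
#' @param block_size features per planted marker block (default 40).
#' @param noise_sd log2 noise standard deviation (default 0.25).
#' @param seed RNG seed.
#' @return A `compendium_spec`.
#' @export
default_compendium_spec <- function(n_features = 400L, block_size = 40L,
                                    noise_sd = 0.25, seed = 1L) {
  groups <- c(BM_myelopoiesis = 34L, blood_subsets = 15L,
              GCSF_leukocytes = 6L, stimulated_monocytes = 15L)
  labels <- names(groups)
  blocks <- lapply(seq_along(labels), function(i) {
    block_spec(
      features = ((i - 1L) * block_size + 1L):(i * block_size),
      high_groups = labels[i],
      effect_log2 = 2
    )
  })
  compendium_spec(groups, n_features, blocks, noise_sd = noise_sd, seed = seed)
}

#' Generate a labeled reference compendium with planted co-expression blocks
#'
#' Produces a log2-scale features-by-samples matrix: every feature sits at
#' `baseline_mean`, block features are raised by their `effect_log2` in the
#' block's `high_groups`, and i.i.d. Gaussian noise of sd `noise_sd` is added.
#' Sample metadata (sample id, group, dataset label) and the planted block
#' membership travel with the matrix.
#'
#' @param spec a [compendium_spec()].
#' @return A `ref_compendium`: list with `exprs` (matrix), `samples`
#'   (data.frame: sample_id, group, dataset) and `truth` (data.frame:
#'   feature_id, block, high_groups).
#' @export
generate_compendium <- function(spec) {
  stopifnot(inherits(spec, "compendium_spec"))
  labels <- names(spec$groups)
  group_of <- rep(labels, times = spec$groups)
  n_samp <- length(group_of)
  feature_ids <- sprintf("F%04d", seq_len(spec$n_features))
  sample_ids <- sprintf("%s_%02d", group_of, unlist(lapply(spec$groups, seq_len)))

  mu <- matrix(spec$baseline_mean, nrow = spec$n_features, ncol = n_samp,
               dimnames = list(feature_ids, sample_ids))
  for (b in spec$blocks) {
    mu[b$features, group_of %in% b$high_groups] <-
      mu[b$features, group_of %in% b$high_groups] + b$effect_log2
  }
  x <- with_rng(spec$seed, {
    mu + matrix(stats::rnorm(length(mu), sd = spec$noise_sd),
                nrow = nrow(mu), ncol = ncol(mu))
  })
  dimnames(x) <- dimnames(mu)

  truth <- data.frame(
    feature_id = feature_ids,
    block = NA_integer_,
    high_groups = NA_character_,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(spec$blocks)) {
    b <- spec$blocks[[i]]
    truth$block[b$features] <- i
    truth$high_groups[b$features] <- paste(b$high_groups, collapse = ";")
  }

  structure(
    list(
      exprs = x,
      samples = data.frame(sample_id = sample_ids, group = group_of,
                           dataset = group_of, stringsAsFactors = FALSE),
      truth = truth
    ),
    class = "ref_compendium"
  )
}

#' @export
print.ref_compendium <- function(x, ...) {
  cat(sprintf("ref_compendium: %d features x %d samples, %d groups (%s)\n",
              nrow(x$exprs), ncol(x$exprs), length(unique(x$samples$group)),
              paste(unique(x$samples$group), collapse = ", ")))
  invisible(x)
}

#' Specify a synthetic case/control cohort with a planted signature
#'
#' @param n_cases,n_controls sample counts per group.
#' @param n_features number of features.
#' @param signature_features integer vector of planted feature indices.
#' @param direction per-feature direction, `"up"` or `"down"`, recycled to
#'   `length(signature_features)`.
#' @param mean_fc target mean linear-scale fold change of up-features
#'   (cases over controls); must satisfy 1 < mean_fc < 4.
#' @param fc_dispersion sd of per-feature log2 fold changes around
#'   `log2(mean_fc)`; 0 plants the identical fold change in every feature.
#' @param noise_sd log2-scale Gaussian noise sd.
#' @param baseline_mean log2 baseline.
#' @param seed RNG seed.
#' @return A `case_control_spec` list, validated.
#' @export
case_control_spec <- function(n_cases, n_controls, n_features,
                              signature_features = integer(0),
                              direction = "up",
                              mean_fc = 1.20, fc_dispersion = 0,
                              noise_sd = 0.30, baseline_mean = 7, seed = 1L) {
  stopifnot_scalar_count(n_cases, "n_cases", 2L)
  stopifnot_scalar_count(n_controls, "n_controls", 2L)
  stopifnot_scalar_count(n_features, "n_features")
  signature_features <- as.integer(signature_features)
  if (anyDuplicated(signature_features)) {
    stop("`signature_features` must be unique", call. = FALSE)
  }
  if (length(signature_features) > 0L &&
      (min(signature_features) < 1L || max(signature_features) > n_features)) {
    stop("`signature_features` out of range [1, n_features]", call. = FALSE)
  }
  direction <- rep_len(match.arg(direction, c("up", "down"), several.ok = TRUE),
                       length(signature_features))
  if (!is.numeric(mean_fc) || length(mean_fc) != 1L || mean_fc <= 1 || mean_fc >= 4) {
    stop("`mean_fc` must satisfy 1 < mean_fc < 4 (direction is per feature)", call. = FALSE)
  }
  if (fc_dispersion < 0 || noise_sd < 0) {
    stop("`fc_dispersion` and `noise_sd` must be >= 0", call. = FALSE)
  }
  structure(
    list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         n_features = as.integer(n_features),
         signature_features = signature_features, direction = direction,
         mean_fc = as.numeric(mean_fc), fc_dispersion = as.numeric(fc_dispersion),
         noise_sd = as.numeric(noise_sd), baseline_mean = as.numeric(baseline_mean),
         seed = as.integer(seed)),
    class = "case_control_spec"
  )
}

#' Generate a case/control expression matrix with a planted signature
#'
#' Cases and controls share a log2 baseline; each planted feature's case mean
#' is shifted by a per-feature log2 fold change drawn as
#' `N(log2(mean_fc), fc_dispersion)` (negated for down-features), then
#' Gaussian noise is added. The returned truth table records, per planted
#' feature, both the structural fold change (`fc_planted`, the mean shift that
#' was built in) and the fold change realized in the emitted matrix
#' (`fc_realized`, the linear ratio of case to control group means).
#'
#' @param spec a [case_control_spec()].
#' @return list with `exprs` (features x samples log2 matrix), `samples`
#'   (data.frame: sample_id, group in {case, control}), and `truth`
#'   (data.frame: feature_id, direction, fc_planted, fc_realized).
#' @export
generate_case_control <- function(spec) {
  stopifnot(inherits(spec, "case_control_spec"))
  n <- spec$n_cases + spec$n_controls
  feature_ids <- sprintf("F%04d", seq_len(spec$n_features))
  group <- rep(c("case", "control"), c(spec$n_cases, spec$n_controls))
  sample_ids <- sprintf("%s_%02d", group, c(seq_len(spec$n_cases), seq_len(spec$n_controls)))

  res <- with_rng(spec$seed, {
    k <- length(spec$signature_features)
    lfc <- numeric(k)
    if (k > 0L) {
      lfc <- stats::rnorm(k, mean = log2(spec$mean_fc), sd = spec$fc_dispersion)
      lfc[spec$direction == "down"] <- -lfc[spec$direction == "down"]
    }
    mu <- matrix(spec$baseline_mean, nrow = spec$n_features, ncol = n)
    if (k > 0L) {
      mu[spec$signature_features, group == "case"] <-
        mu[spec$signature_features, group == "case"] + lfc
    }
    x <- mu + matrix(stats::rnorm(length(mu), sd = spec$noise_sd),
                     nrow = nrow(mu), ncol = ncol(mu))
    list(x = x, lfc = lfc)
  })
  x <- res$x
  dimnames(x) <- list(feature_ids, sample_ids)

  k <- length(spec$signature_features)
  truth <- data.frame(
    feature_id = character(0), direction = character(0),
    fc_planted = numeric(0), fc_realized = numeric(0),
    stringsAsFactors = FALSE
  )
  if (k > 0L) {
    m_case <- rowMeans(x[spec$signature_features, group == "case", drop = FALSE])
    m_ctrl <- rowMeans(x[spec$signature_features, group == "control", drop = FALSE])
    truth <- data.frame(
      feature_id = feature_ids[spec$signature_features],
      direction = spec$direction,
      fc_planted = 2^res$lfc,
      fc_realized = 2^(m_case - m_ctrl),
      stringsAsFactors = FALSE
    )
  }
  list(
    exprs = x,
    samples = data.frame(sample_id = sample_ids, group = group, stringsAsFactors = FALSE),
    truth = truth
  )
}

#' Convert a log2 expression matrix to RNA-seq-like counts
#'
#' Exponentiates the log2 matrix and Poisson-samples each cell, emulating a
#' count-scale cohort driven by the same underlying means.
#'
#' @param x log2-scale matrix.
#' @param seed RNG seed.
#' @return integer matrix of the same shape.
#' @export
as_count_matrix <- function(x, seed = 1L) {
  check_finite_matrix(x, "expression matrix")
  counts <- with_rng(seed, {
    matrix(stats::rpois(length(x), lambda = 2^x), nrow = nrow(x), ncol = ncol(x))
  })
  dimnames(counts) <- dimnames(x)
  counts
}

#' Generate a synthetic serum-marker table with known group shifts
#'
#' @param group_means named numeric vector of per-group means (linear scale).
#' @param group_sds per-group spread: sd for `distribution = "normal"`,
#'   sdlog for `"lognormal"` (in which case `group_means` is the median and
#'   the values are `exp(rnorm(log(mean), sdlog))`). `sd = 0` is the
#'   degenerate limit in which every value equals the group mean; negative
#'   sds are rejected.
#' @param group_ns named integer vector of per-group sample counts (all >= 2).
#' @param distribution `"normal"` or `"lognormal"`.
#' @param analyte analyte name recorded in the table.
#' @param seed RNG seed.
#' @return data.frame: sample_id, group, analyte, value.
#' @export
generate_serum_markers <- function(group_means, group_sds, group_ns,
                                   distribution = c("normal", "lognormal"),
                                   analyte = "marker", seed = 1L) {
  distribution <- match.arg(distribution)
  labels <- names(group_means)
  if (is.null(labels)) stop("`group_means` must be named by group", call. = FALSE)
  if (!identical(labels, names(group_sds)) || !identical(labels, names(group_ns))) {
    stop("`group_means`, `group_sds`, `group_ns` must share the same group names",
         call. = FALSE)
  }
  if (any(group_sds < 0)) stop("group sds must be >= 0", call. = FALSE)
  if (any(group_ns < 2L)) stop("every group needs n >= 2", call. = FALSE)

  values <- with_rng(seed, {
    unlist(lapply(labels, function(g) {
      n <- group_ns[[g]]
      if (distribution == "normal") {
        stats::rnorm(n, mean = group_means[[g]], sd = group_sds[[g]])
      } else {
        exp(stats::rnorm(n, mean = log(group_means[[g]]), sd = group_sds[[g]]))
      }
    }), use.names = FALSE)
  })
  group <- rep(labels, times = group_ns)
  data.frame(
    sample_id = sprintf("%s_%02d", group, unlist(lapply(group_ns, seq_len))),
    group = group,
    analyte = analyte,
    value = values,
    stringsAsFactors = FALSE
  )
}
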