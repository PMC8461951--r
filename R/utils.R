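#' @keywords internal
"_PACKAGE"

# Run `expr` under a Mersenne-Twister stream seeded with `seed`, restoring the
# caller's RNG state afterwards. All stochastic generators in the package go
# through this, so fixtures are reproducible and no global state leaks.
with_rng <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

# Consistent matrix check used by every stage that refuses non-finite input.
check_finite_matrix <- function(x, what = "matrix") {
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    rn <- rownames(x) %||% as.character(seq_len(nrow(x)))
    cn <- colnames(x) %||% as.character(seq_len(ncol(x)))
    cells <- apply(utils::head(bad, 10L), 1L, function(ij) {
      sprintf("[%s, %s]", rn[ij[1L]], cn[ij[2L]])
    })
    stop(sprintf(
      "%s contains %d non-finite value(s), e.g. %s",
      what, nrow(bad), paste(cells, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic numeric formatting shared by all TSV writers so that reruns of
# the pipeline are byte-identical.
format_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 15, format = "g"))
}
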