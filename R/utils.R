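# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored on exit so library code never perturbs user RNG.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a distinct, stable child seed from a base seed (kept below 2^31).
child_seed <- function(seed, offset) {
  (as.integer(seed) + 104729L * as.integer(offset)) %% 2147483647L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_asv_table <- function(x, arg = "table") {
  if (!is.matrix(x) || !is.numeric(x))
    stopf("`%s` must be a numeric matrix (samples x taxa)", arg)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stopf("`%s` must have sample rownames and taxon colnames", arg)
  if (anyDuplicated(rownames(x))) stopf("duplicate sample ids in `%s`", arg)
  if (anyDuplicated(colnames(x))) stopf("duplicate taxon ids in `%s`", arg)
  if (any(x < 0)) stopf("`%s` contains negative counts", arg)
  if (any(abs(x - round(x)) > 1e-8)) stopf("`%s` contains non-integer counts", arg)
  invisible(x)
}

# Lower-triangle (i < j) index pairs of an n x n matrix, as a 2-column matrix.
pair_index <- function(n) {
  if (n < 2) return(matrix(integer(0), ncol = 2))
  t(combn(n, 2L))
}
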