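# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive `n` independent sub-seeds (< 2^31) from a master seed.
.derive_seeds <- function(seed, n) {
  .with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

.check_metal_names <- function(x, what) {
  if (is.null(names(x)) || !all(.metals %in% names(x)))
    stop(sprintf("'%s' must be a named vector covering metals: %s",
                 what, paste(.metals, collapse = ", ")), call. = FALSE)
  bad <- setdiff(names(x), .metals)
  if (length(bad))
    stop(sprintf("unknown metal key(s) in '%s': %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  x[.metals]
}

.stopifnot_positive <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop(sprintf("'%s' must be strictly positive", what), call. = FALSE)
  invisible(x)
}
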