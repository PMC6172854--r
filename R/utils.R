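## Internal helpers.

# Evaluate expr under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library code never perturbs user RNG.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a master seed and a stream index, staying inside
# the positive 32-bit integer range.
childSeed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + 11 * stream) %% 2147483647)
}

.matchCondition <- function(condition) {
  match.arg(condition, c("EO", "EC"))
}

.assertCols <- function(df, cols, what = "table") {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
  invisible(df)
}
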