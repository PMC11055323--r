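# internal helpers shared across modules

# run expr under a local RNG state seeded with `seed`, restoring the caller's
# stream afterwards so library code never perturbs user-level randomness
with_seed <- function(seed, expr) {
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
  expr
}

# derive a child seed from a parent seed and a stream index; kept < 2^31
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + as.numeric(stream) * 69621) %% 2147483587
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (strict_lower && x <= lower)
    stopf("`%s` must be > %g (got %g)", name, lower, x)
  if (!strict_lower && x < lower)
    stopf("`%s` must be >= %g (got %g)", name, lower, x)
  if (x > upper) stopf("`%s` must be <= %g (got %g)", name, upper, x)
  x
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)
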