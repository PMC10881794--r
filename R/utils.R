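# Internal helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library calls never perturb user simulations.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a stream of child seeds from one master seed (kept within the
# 32-bit integer range R requires).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

is_binary <- function(x) all(x %in% c(0, 1))

# sample() treats a scalar first argument as 1:x; this picks uniformly from
# the elements of x regardless of its length.
sample_one <- function(x) x[sample.int(length(x), 1L)]
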