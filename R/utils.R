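# internal helpers

# evaluate expr with a local RNG state seeded by `seed`, restoring the
# caller's state afterwards; all randomized operations go through this so no
# hidden global state survives a call
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# deterministic child seed derived from a master seed and a stage counter
child_seed <- function(seed, stage) {
  (as.numeric(seed) * 1000 + stage) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a
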