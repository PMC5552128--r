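# internal helpers

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG afterwards. seed = NULL means: use the current RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Derive a child seed from a base seed and one or more indices, staying below
# 2^31. Deterministic; used so that every run in a grid has an independent,
# reproducible stream.
derive_seed <- function(base, ...) {
  idx <- c(...)
  s <- as.double(base %% 2147483647L)
  for (k in idx) {
    s <- (s * 48271 + as.double(k) * 16807 + 1) %% 2147483647
  }
  as.integer(max(1, s))
}

stop_invalid <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "serpens_invalid_parameter")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
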