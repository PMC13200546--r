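`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library functions never perturb user code.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic child seed < 2^31 derived from (seed, tag).
derive_seed <- function(seed, tag) {
  h <- 0
  for (ch in utf8ToInt(paste0(tag, ":", seed))) {
    h <- (h * 31 + ch) %% 2147483629
  }
  as.integer(h + 1)
}
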