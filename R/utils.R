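# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring global RNG state afterwards
# so package functions never leak random-number state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Column-major linear index (first variable fastest) of integer state codes.
# `codes` is an n x k matrix (or vector) of 1-based codes, `card` the per-column
# cardinalities. Returns 1-based linear indices.
linear_index <- function(codes, card) {
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = 1L)
  if (ncol(codes) == 0L) return(rep(1L, nrow(codes)))
  strides <- cumprod(c(1, card[-length(card)]))
  as.integer(round(as.vector((codes - 1) %*% strides) + 1))
}

fmt_num <- function(x) sprintf("%.17g", x)
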