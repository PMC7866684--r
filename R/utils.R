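## Small internal helpers.

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring
# the caller's state afterwards.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a named substream seed from a master seed, keeping the result
# a valid 32-bit integer.
.substream <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 1103 + h) %% 2147483647)
}

.soft_threshold <- function(x, lambda) sign(x) * pmax(abs(x) - lambda, 0)
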