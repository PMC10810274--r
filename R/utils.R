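# Deterministic per-entity random streams.
#
# Every stochastic component of the package draws from a stream keyed by
# (seed, entity label), so that generating a subset of a design (fewer days,
# fewer participants) reproduces exactly the records it shares with the full
# design, and so that validation iterations are reproducible independently
# of evaluation order.

# 31-ary polynomial string hash folded into [0, 2^31 - 2]; double arithmetic
# stays below 2^53 so the modular reduction is exact.
hash_seed <- function(seed, key) {
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under the stream (seed, key), restoring the caller's RNG
# state afterwards so package internals never perturb the global stream.
with_stream <- function(seed, key, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(hash_seed(seed, key))
  expr
}

stream_rnorm <- function(n, seed, key, sd = 1) {
  if (sd == 0) return(numeric(n))
  with_stream(seed, key, stats::rnorm(n, sd = sd))
}

stream_shuffle <- function(x, seed, key) {
  with_stream(seed, key, sample(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
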