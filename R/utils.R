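# internal helpers shared across modules

# evaluate expr under a temporary RNG seed, restoring the caller's state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  eval.parent(substitute(expr))
}

# deterministic 31-bit polynomial hash of a string, optionally mixed with
# an integer seed; used to key per-accession random draws. Multiplier kept
# small so intermediate products stay exact in double precision.
stringHash <- function(x, seed = 0L) {
  vapply(x, function(s) {
    h <- 17
    for (b in utf8ToInt(s)) h <- (h * 48271 + b) %% 2147483647
    as.integer((h + (as.numeric(seed) %% 2147483647) * 69069) %% 2147483647)
  }, integer(1L), USE.NAMES = FALSE)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
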