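# Internal helpers shared across modules.

# Deterministic seed fan-out: one master seed plus a string label yields an
# independent, reproducible stream seed below 2^31. Avoids coupling the RNG
# streams of different pipeline stages / participants.
derive_seed <- function(seed, ...) {
  lab <- paste(c(...), collapse = "/")
  h <- seed %% 2147483647
  for (ch in utf8ToInt(lab)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h %% 2147483646L + 1L)
}

# Evaluate `code` under `seed` (when non-NULL), restoring the caller's RNG
# state afterwards so library code never clobbers a user's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
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

# sample() without the length-1 surprise.
sample_vec <- function(x, size = length(x), replace = FALSE) {
  x[sample.int(length(x), size = size, replace = replace)]
}

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))
warnf <- function(fmt, ...) warn(sprintf(fmt, ...))
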