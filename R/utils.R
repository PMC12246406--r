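# shared internal helpers

# Seed the RNG inside the calling function only: the previous global RNG
# state is restored when the caller exits, so seeded package functions do
# not disturb a user's random stream.
local_rng <- function(seed, envir = parent.frame()) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    restore <- if (is.null(old)) {
      quote(rm(".Random.seed", envir = globalenv()))
    } else {
      bquote(assign(".Random.seed", .(old), envir = globalenv()))
    }
    do.call(on.exit, list(restore, add = TRUE), envir = envir)
    set.seed(seed)
  }
  invisible(seed)
}

# Stable small-integer hash of a character string, for deriving per-item
# seeds from (id, seed) pairs without consuming the global stream.
string_seed <- function(..., base = 0L) {
  s <- paste(..., sep = "\r")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483563
  as.integer((h + as.numeric(base)) %% 2147483563)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
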