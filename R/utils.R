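# Internal helpers: seeded RNG streams and small numeric utilities.
#
# All stochastic code in the package draws from explicit stream objects so that
# model randomness (initialisation, batching, dropout) and privacy noise come
# from independent, reproducible generators and nothing leaks into or out of
# the user's global RNG state.

# A mutable RNG stream seeded once; rng_eval() runs a thunk under the stream
# and stores the advanced state back, always restoring the caller's RNG.
rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  e$seed <- as.integer(seed)
  e$blob <- NULL
  class(e) <- "privsurv_rng"
  e
}

rng_eval <- function(state, fn) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  if (is.null(state$blob)) {
    set.seed(state$seed)
  } else {
    assign(".Random.seed", state$blob, envir = genv)
  }
  on.exit({
    state$blob <- get(".Random.seed", envir = genv)
    if (had) assign(".Random.seed", old, envir = genv)
    else rm(".Random.seed", envir = genv)
  }, add = TRUE)
  fn()
}

# Run a thunk under a fixed seed, restoring the caller's RNG afterwards.
with_seed <- function(seed, fn) rng_eval(rng_stream(seed), fn)

# Population (divide-by-n) variance; the screening convention used throughout.
pop_var <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  m <- mean(x)
  sum((x - m)^2) / n
}

# Nearest-rank percentile of a numeric vector (value at ceil(p/100 * n) of the
# ascending sort), the convention used for relevance summaries and interval
# cuts.
nearest_rank <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  idx <- pmax(1L, as.integer(ceiling(p / 100 * n)))
  s[pmin(idx, n)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
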