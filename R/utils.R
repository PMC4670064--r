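# internal helpers shared across modules

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic sub-seed from a master seed and a stage tag, so pipeline
# stages can be rerun independently while all randomness flows from one
# integer. Kept below 2^31 - 1.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% 1000000007
  as.integer((abs(seed) * 2654435761 + h * 97 + 17) %% .Machine$integer.max)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# trapezoidal rule on (x, y) sorted by x
trapz <- function(x, y) {
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  if (length(x) < 2L) return(0)
  sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
}

stop_named <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_named <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
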