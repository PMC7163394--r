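## Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a deterministic substream seed
#'
#' All randomness in the package flows from one user-supplied seed; named
#' substreams keep stages (goat traits, each goat-day, clustering, ...)
#' reproducible and independent of one another. The result is always a
#' positive integer below 2^31 so it is a valid argument to [set.seed()].
#'
#' @param seed base integer seed.
#' @param ... labels (coerced to character) identifying the substream.
#' @return an integer seed.
#' @export
substream_seed <- function(seed, ...) {
  key <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                      character(1)), collapse = "/")
  m32 <- 4294967296
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% m32
  mixed <- fmix32((mul32(as.numeric(seed) %% m32, 2654435761) + h) %% m32)
  as.integer(mixed %% 2147483646 + 1)
}

## 32-bit helpers in double arithmetic (R has no unsigned 32-bit integers).
## fmix32 is the murmur3 avalanche finalizer: related raw seeds (e.g. the
## near-consecutive hashes of per-cell labels) must not map to related
## RNG streams, because Mersenne-Twister's first draws correlate across
## similar seeds.
mul32 <- function(a, b) {
  hi <- floor(a / 65536)
  lo <- a %% 65536
  ((hi * b %% 65536) * 65536 + lo * b) %% 4294967296
}

xor32 <- function(a, b) {
  r <- 0; p <- 1
  for (i in 1:32) {
    r <- r + p * ((a + b) %% 2)
    a <- floor(a / 2); b <- floor(b / 2); p <- p * 2
  }
  r
}

fmix32 <- function(h) {
  h <- xor32(h, floor(h / 65536))
  h <- mul32(h, 2246822507)
  h <- xor32(h, floor(h / 8192))
  h <- mul32(h, 3266489909)
  xor32(h, floor(h / 65536))
}

## Evaluate expr under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
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

stop_domain <- function(...) stop(..., call. = FALSE)

## Column-presence check for data.frame inputs.
need_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop_domain(what, " is missing required column(s): ", paste(miss, collapse = ", "))
  invisible(df)
}
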