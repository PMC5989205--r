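# internal helpers: seeded RNG scoping and seed derivation

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG state is untouched.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Derive a stage seed from a run seed
#'
#' One global seed fans out to per-stage seeds by hashing the stage name
#' (31-based string hash mod 2^31 - 1), so every stage is independently
#' reproducible from the run seed alone.
#'
#' @param seed integer run seed.
#' @param stage character stage label (e.g. \code{"plasma/2"}).
#' @return an integer in \code{[1, 2^31 - 2]}.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% m
  s <- (abs(as.numeric(seed)) %% m + h) %% m
  as.integer(s %% (m - 1) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_hapdose <- function(...) stop(sprintf(...), call. = FALSE)

# 32-bit polynomial string hash, returned as 8 hex chars; used to stamp
# configs into reports without external digest dependencies.
config_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 216613626
  for (ch in utf8ToInt(x)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}
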