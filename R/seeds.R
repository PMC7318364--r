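#' Derive a reproducible integer seed from a master seed and a key
#'
#' Counter-based seed derivation so that every (condition, replication)
#' pair gets its own RNG stream: adding conditions to a study never
#' perturbs the streams of existing ones.  The derived seed is a
#' deterministic hash of the master seed, a string key and a counter,
#' reduced modulo 2^31 - 1 so it is always a valid R integer seed.
#'
#' @param master integer master seed.
#' @param key character scalar naming the stream (e.g. a condition label).
#' @param counter non-negative integer, typically a replication index.
#' @return a single integer in [1, 2^31 - 2].
#' @examples
#' derive_seed(1, "scenario=A/n=500", 7)
#' @export
derive_seed <- function(master, key = "", counter = 0L) {
  stopifnot(length(master) == 1L, length(key) == 1L, length(counter) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  h <- (as.numeric(master) %% m)
  # string hash, polynomial rolling; all arithmetic kept < 2^53
  for (ch in utf8ToInt(as.character(key))) {
    h <- (h * 131 + ch) %% m
  }
  h <- (h * 48271 + as.numeric(counter) * 69621 + 1) %% m
  # one multiplicative mixing step (Lehmer-style)
  h <- (h * 16807) %% m
  as.integer(h %% (m - 2) + 1)
}

# run expr with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
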