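#' Derive a stream seed from a root seed and a stage label
#'
#' All stochastic operations in the package derive their own seed from a
#' single root seed plus a short label naming the stream. Reruns of one stage
#' are therefore reproducible without replaying earlier stages, and two
#' stages never share a random stream by accident.
#'
#' The derivation is a Lehmer-style mix modulo 2^31 - 1: the label is folded
#' into an integer with a base-31 rolling hash and combined with the root
#' seed; every intermediate stays below 2^53 so the arithmetic is exact in
#' doubles.
#'
#' @param seed Root seed, a single non-negative integer below 2^31.
#' @param tag Character label of the stream (e.g. "reads", "flow").
#' @return A single integer in [1, 2^31 - 2], usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1L, "reads")
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0, seed < 2^31)
  stopifnot(is.character(tag), length(tag) == 1L, nzchar(tag))
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (code in utf8ToInt(tag)) h <- (h * 31 + code) %% m
  out <- ((seed %% m) * 48271 + h * 69621 + 1) %% m
  as.integer(if (out == 0) 1 else out)
}

# Run `expr` under a derived seed, restoring the caller's RNG state after.
with_stream <- function(seed, tag, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, tag))
  expr
}
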