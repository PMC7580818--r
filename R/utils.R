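#' Derive a child seed from a root seed
#'
#' Deterministic 31-bit integer stream: stage `i` of a run seeded with
#' `seed` always receives the same child seed, and different stages get
#' effectively independent ones (multiplicative Lehmer step). All
#' randomness in the package flows from one root seed through this
#' function.
#'
#' @param seed root seed (positive integer).
#' @param i stage/replicate index (>= 0).
#' @return a positive integer < 2^31.
#' @export
childSeed <- function(seed, i) {
  m <- 2147483647  # 2^31 - 1
  x <- (as.numeric(seed) %% m)
  if (x <= 0) x <- x + m - 1
  for (k in seq_len(3)) x <- (x * 48271 + i + k) %% m
  as.integer(x + 1)
}
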