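#' Derive a reproducible sub-seed from a master seed and labels
#'
#' Monte Carlo runs that mix several strategies, scenarios and batches need
#' independent random streams that do not shift when one component is added
#' or removed. `derive_seed()` hashes the master seed together with an
#' arbitrary set of labels (strategy name, scenario name, batch index, ...)
#' into a stable 31-bit seed, so each (seed, labels) combination always maps
#' to the same sub-stream.
#'
#' @param seed Integer master seed.
#' @param ... Further labels (coerced to character) identifying the stream.
#' @return A single integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' derive_seed(1, "rand", "A", 3)
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  key <- paste(c(format(seed), vapply(list(...), as.character, character(1))),
               collapse = "\x1f")
  # polynomial rolling hash mod a Mersenne prime; stays in exact double range
  m <- 2147483647
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 131 + b) %% m
  as.integer(h %% (m - 2L) + 1L)
}
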