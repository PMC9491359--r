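#' Derive a reproducible sub-seed from a global seed and labels
#'
#' Deterministically maps a global seed plus an arbitrary set of labels
#' (stage name, subject index, condition id, trial index, ...) to an integer
#' seed in `[0, 2^31 - 2]`. Keying sub-seeds by label rather than by draw
#' order means that, e.g., adding subjects to a cohort does not perturb the
#' data of existing subjects.
#'
#' A simple polynomial rolling hash over the UTF-8 bytes of the
#' concatenated labels, mod the Mersenne prime 2^31 - 1. All arithmetic
#' stays below 2^53 so it is exact in doubles.
#'
#' @param seed integer global seed.
#' @param ... labels (coerced to character) identifying the consumer.
#' @return a single integer usable with [set.seed()].
#' @examples
#' derive_seed(1, "trial", 3, 2) # stable across sessions
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(format(as.integer(seed)), vapply(list(...), format, "")),
               collapse = "\x1f")
  h <- as.integer(seed) %% 2147483647
  for (b in utf8ToInt(key)) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}
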