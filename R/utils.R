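#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from one global seed; each stage and
#' well draws from its own sub-stream so that, e.g., adding noise to one well
#' cannot perturb the sampling of another. The derivation is a small integer
#' hash of the seed and the stream tags, kept strictly below 2^31.
#'
#' @param seed integer base seed.
#' @param ... character or numeric tags naming the sub-stream.
#' @return a single integer seed.
#' @examples
#' deriveSeed(1, "traces", "A1")
#' @export
deriveSeed <- function(seed, ...) {
  tags <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- as.double(seed) %% 2147483647
  for (k in utf8ToInt(tags)) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

## stop() wrapper that tags configuration errors with the offending field
configError <- function(field, why) {
  stop(sprintf("invalid configuration: '%s' %s", field, why), call. = FALSE)
}
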