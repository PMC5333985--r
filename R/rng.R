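#' Derive a reproducible substream seed from a master seed and a label
#'
#' One master seed drives a whole run; per-module substreams (panel
#' generation, fate decisions, hypermutation, ...) are derived by mixing the
#' master seed with a stream label, so module-level tests and full runs replay
#' identically. The mix is a small multiplicative hash kept below 2^31 - 1.
#'
#' @param seed master seed (integer-valued)
#' @param name substream label
#' @return an integer seed in \[1, 2^31 - 2\]
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed),
            is.character(name), length(name) == 1)
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% m
  s <- ((abs(seed) %% m) * 69069 + h * 40692 + 1) %% m
  as.integer(if (s == 0) 1 else s)
}
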