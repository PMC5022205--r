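#' Derive a reproducible substream seed
#'
#' All simulators draw their randomness from one master seed via named
#' substreams, so that regenerating one output file never perturbs another.
#' The derivation is a small deterministic hash of the stream name folded
#' into the master seed; results stay within 32-bit integer range.
#'
#' @param seed Master seed (integer).
#' @param stream Character stream name, e.g. `"dhs"`, `"variants"`.
#' @return Integer seed for `set.seed()`.
#' @export
substream_seed <- function(seed, stream) {
  h <- 0
  for (code in utf8ToInt(stream)) h <- (h * 131 + code) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

with_substream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, stream))
  force(expr)
}
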