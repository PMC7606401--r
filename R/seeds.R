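#' Derive independent sub-stream seeds from one master seed
#'
#' All randomness in the package flows from a single master seed that is split
#' into named sub-streams (e.g. sequence generation, RT noise, accuracy,
#' neuropsych scores), so that individual pipeline stages are reproducible in
#' isolation: changing how many random numbers one stage draws never perturbs
#' another stage.
#'
#' @param seed Integer master seed.
#' @param streams Character vector of sub-stream names.
#' @return Named integer vector of seeds, one per stream.
#' @examples
#' substream_seeds(1, c("sequence", "noise"))
#' @export
substream_seeds <- function(seed, streams) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(streams), length(streams) >= 1L)
  seeds <- withr::with_seed(
    as.integer(seed),
    sample.int(.Machine$integer.max - 1L, length(streams))
  )
  setNames(as.integer(seeds), streams)
}

## Run `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
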