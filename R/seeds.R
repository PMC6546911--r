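## Deterministic seed derivation: one master seed spawns per-stage,
## per-trace child seeds so every stochastic stage is reproducible in
## isolation. SplitMix64-style integer mixing, reduced to the 31-bit
## positive range set.seed() accepts.

#' Derive a child seed from a master seed
#'
#' Deterministically mixes a master seed with a stage label and an index so
#' independent stages and traces get decorrelated, reproducible streams.
#'
#' @param master integer master seed.
#' @param stage character stage label (e.g. "simulate", "render").
#' @param index integer index within the stage (default 0).
#' @return a positive integer < 2^31 suitable for [set.seed()].
#' @export
#' @examples
#' childSeed(1, "simulate", 5)
childSeed <- function(master, stage, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  h <- as.double(master) %% 2147483647
  for (b in c(utf8ToInt(as.character(stage)), as.double(index) + 1)) {
    # 64-bit-free multiplicative mixing kept inside double precision
    h <- (h * 48271 + b * 10007 + 12345) %% 2147483647
    h <- (h * 69621) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

## run a block under a local, restored RNG state
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
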