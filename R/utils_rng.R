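# Seed management. All stochastic functions take an explicit seed and leave
# the caller's RNG state untouched; a master seed fans out to fixed
# per-stage streams so pipeline stages are independently reproducible.

#' Evaluate code under a fixed seed without disturbing the global RNG
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Derive a stage-specific seed from a master seed
#'
#' Deterministic splitting rule: `(master * 48271 + 9973 * stage) mod
#' (2^31 - 1)`, mapped into 1..2^31-2 so it is always a valid 32-bit seed.
#'
#' @param master integer master seed.
#' @param stage small integer identifying the pipeline stage.
#' @return derived integer seed.
#' @export
derive_seed <- function(master, stage = 0L) {
  m <- 2147483647
  s <- (as.numeric(master) %% m) * 48271 + 9973 * (as.numeric(stage) + 1)
  as.integer(s %% (m - 2) + 1)
}
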