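## internal helpers

## Evaluate expr under a temporary RNG seed, restoring prior RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    set.seed(seed)
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
  }
  force(expr)
}

## Derive a stage seed from a master seed; keeps results < 2^31.
derive_seed <- function(seed, stage) {
  offsets <- c(simulate = 101, qc = 211, popgen = 307, pca = 401,
               hybrid = 503, scan = 601, panel = 701, morpho = 809)
  off <- if (stage %in% names(offsets)) offsets[[stage]] else
    sum(utf8ToInt(stage))
  as.integer((as.double(seed) * 2654435761 + off * 97) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
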