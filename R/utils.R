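#' @importFrom stats pnorm rnorm rpois runif
#' @importFrom utils write.table
NULL

## Evaluate expr under a temporary RNG seed, restoring global RNG state.
## seed = NULL leaves the RNG stream untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

## Short provenance string identifying a radius map: shape, pitch and beam
## center at full precision. Not cryptographic; used to detect geometry
## mismatch between sparsification and densification.
geometryHash <- function(dim, beamCenter, pixelSize) {
  sprintf("r%dx%d_p%.17g_c%.17g_%.17g", dim[1L], dim[2L], pixelSize,
          beamCenter[1L], beamCenter[2L])
}
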