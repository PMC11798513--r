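#' Reconstruct a dense frame from its sparse representation
#'
#' Restores the retained pixels bit-exact and synthesizes the background for
#' the rest from the stored radial profile: the bin mean as is
#' (`noise = "none"`), with Gaussian noise of the stored per-bin sigma
#' (`"gaussian"`), or as Poisson draws of the bin mean (`"poisson"`; bins with
#' a negative mean fall back to Gaussian with a warning). Masked pixels and
#' pixels whose bin has no valid background are set to the sentinel value -1:
#' shaded regions are never reconstructed properly and should stay masked in
#' downstream reduction.
#'
#' @param sparse a [SparseFrame-class].
#' @param noise background noise model: `"none"`, `"gaussian"` or
#'   `"poisson"`.
#' @param seed integer seed making the reconstruction deterministic; NULL
#'   draws from the current RNG stream.
#' @param integerOutput if TRUE, the background is rounded to integer counts
#'   and truncated at 0 (count-like output); retained pixels are left exact.
#' @return Numeric matrix of the frame shape.
#' @examples
#' \dontrun{dense <- densify(readSparse("sparse.h5")[[1]], noise = "gaussian",
#'                           seed = 7)}
#' @export
densify <- function(sparse, noise = c("none", "gaussian", "poisson"),
                    seed = NULL, integerOutput = FALSE) {
  noise <- match.arg(noise)
  stopifnot(is(sparse, "SparseFrame"))
  nr <- sparse@dim[1L]; nc <- sparse@dim[2L]
  nB <- length(sparse@backgroundMean)
  ## rebuild the pixel -> bin map from the stored geometry
  g <- DetectorGeometry(nr, nc, pixelSize = sparse@pixelSize,
                        beamCenter = sparse@beamCenter)
  r <- buildRadiusMap(g)
  bin <- findInterval(r, sparse@binEdges, rightmost.closed = TRUE)
  bin[bin < 1L | bin > nB] <- NA_integer_
  mu <- sparse@backgroundMean[bin]
  sd <- sparse@backgroundStd[bin]
  bad <- is.na(bin) | !is.finite(mu) | !is.finite(sd)
  out <- withSeed(seed, {
    bg <- switch(noise,
      none = mu,
      gaussian = mu + rnorm(length(mu), 0, ifelse(bad, 0, sd)),
      poisson = {
        neg <- !bad & mu < 0
        if (any(neg)) {
          warning("bins with negative background mean: ",
                  "using gaussian noise there")
          x <- numeric(length(mu))
          ok <- !bad & !neg
          x[ok] <- rpois(sum(ok), mu[ok])
          x[neg] <- mu[neg] + rnorm(sum(neg), 0, sd[neg])
          x
        } else {
          x <- numeric(length(mu))
          x[!bad] <- rpois(sum(!bad), mu[!bad])
          x
        }
      })
    bg
  })
  if (integerOutput) out <- pmax(round(out), 0)
  out[bad] <- -1
  dense <- matrix(out, nr, nc)
  dense[sparse@mask] <- -1
  if (length(sparse@pixelIndices)) {
    flat <- sparse@pixelIndices              # row-major 0-based
    rowi <- flat %/% nc + 1L
    coli <- flat %% nc + 1L
    dense[cbind(rowi, coli)] <- sparse@pixelValues
  }
  dense
}
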