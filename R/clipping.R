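#' Adaptive clipping cutoff (Chauvenet variant)
#'
#' Rejection threshold, in sigma units, at which a normally distributed ring
#' of N pixels would be expected to lose just one member:
#' `t(N) = sqrt(2 * ln(N / sqrt(2 * pi)))`. The threshold therefore adapts to
#' the ring population — about 2.7 for 100 pixels, 3.5 for 1000 — and is
#' recomputed as clipping shrinks the ensemble. For N below `sqrt(2 * pi)`
#' (where the expression has no real value) the result is clamped at 0;
#' [sigmaClip()] never clips such tiny bins anyway.
#'
#' @param nPixels integer vector of ring populations.
#' @return Numeric vector of thresholds in sigma units, monotonically
#'   increasing in `nPixels`.
#' @examples
#' round(chauvenetCutoff(c(100, 1000)), 1)  # 2.7, 3.5
#' @export
chauvenetCutoff <- function(nPixels) {
  sqrt(2 * pmax(log(nPixels / sqrt(2 * pi)), 0))
}

#' Iterative sigma clipping per radial bin
#'
#' Robust background estimation: per bin, the mean and pixel-level deviation
#' are computed under the clipping error model (the azimuthal ring-variance
#' model when `errorModel` is `"azimuthal"` or `"hybrid"`), pixels whose
#' intensity differs from the ring mean by more than `n * sigma` are discarded
#' (two-sided: positive outliers are Bragg peaks, negative ones shadows), and
#' the statistics are recomputed. Iteration stops as soon as no pixel is
#' discarded or `maxIter` is reached — a handful of iterations is typical.
#' With `snr = "auto"` the cutoff is [chauvenetCutoff()] of the current bin
#' population, recomputed as it shrinks. Ties at exactly `n * sigma` are
#' retained. Bins with fewer than 3 pixels are never clipped; bins emptied of
#' all pixels are flagged invalid with a warning, never an error.
#'
#' The returned profile uses the configured reporting model: `"poisson"` and
#' `"azimuthal"` report their own statistics on the inlier set, while
#' `"hybrid"` clips with the azimuthal model (resilient to bimodal rings,
#' where a Poissonian sigma would reject everything) and reports Poisson
#' uncertainties on the trimmed, now mono-modal ensemble.
#'
#' @param frame a [PreprocessedFrame-class].
#' @param bins a [BinAssignment-class].
#' @param config a [ClipConfig()].
#' @param varianceFloor minimum per-pixel variance for hybrid reporting.
#' @return A [ClipResult-class].
#' @examples
#' g <- DetectorGeometry(64, 64)
#' ba <- buildBinAssignment(buildRadiusMap(g), nBins = 16)
#' pf <- preprocessFrame(matrix(rpois(64 * 64, 50), 64, 64))
#' cr <- sigmaClip(pf, ba, ClipConfig(snr = 3))
#' sum(inlierMask(cr))
#' @export
sigmaClip <- function(frame, bins, config = ClipConfig(), varianceFloor = 1) {
  stopifnot(is(frame, "PreprocessedFrame"), is(bins, "BinAssignment"),
            is(config, "ClipConfig"))
  validObject(config)
  if (!identical(dim(frame@signal), dim(bins@pixelBin)))
    stop("bin assignment does not match the frame shape")
  clipModel <- if (config@errorModel == "hybrid") "azimuthal"
               else config@errorModel
  nb <- bins@nBins
  keep <- !frame@mask & !is.na(bins@pixelBin)
  ## flat working vectors over the initially eligible pixels
  idx0 <- which(keep)
  b0 <- bins@pixelBin[idx0]
  nrm <- frame@norm[idx0]
  cf <- bins@coefficients[idx0]
  v <- frame@signal[idx0] / nrm
  w <- cf * nrm
  sig2 <- frame@variance[idx0]
  alive <- rep(TRUE, length(idx0))
  iterations <- integer(nb)
  startCount <- as.integer(.binsum(rep(1, length(idx0)), b0, nb))
  for (iter in seq_len(config@maxIter)) {
    bi <- b0[alive]
    O <- .binsum(w[alive], bi, nb)
    count <- .binsum(rep(1, sum(alive)), bi, nb)
    mu <- ifelse(O > 0, .binsum(w[alive] * v[alive], bi, nb) / O, NA_real_)
    if (clipModel == "azimuthal") {
      dev <- v[alive] - mu[bi]
      std <- sqrt(pmax(.binsum(w[alive] * dev * dev, bi, nb), 0) /
                    pmax(O, .Machine$double.xmin))
    } else {
      O2 <- .binsum(w[alive]^2, bi, nb)
      S <- .binsum((cf[alive] * cf[alive]) * sig2[alive], bi, nb)
      std <- sqrt(S * O2) / pmax(O, .Machine$double.xmin) # sem * sqrt(Neff)
    }
    thr <- if (config@auto) chauvenetCutoff(count) else rep(config@snr, nb)
    ## bins too small (or already stable) are left untouched
    clippable <- count >= 3
    reject <- alive
    reject[alive] <- clippable[bi] &
      abs(v[alive] - mu[bi]) > thr[bi] * std[bi]
    if (!any(reject)) break
    changed <- unique(b0[reject])
    iterations[changed] <- iter
    alive[reject] <- FALSE
  }
  inlier <- matrix(FALSE, nrow(frame@signal), ncol(frame@signal))
  inlier[idx0[alive]] <- TRUE
  endCount <- as.integer(.binsum(rep(1, sum(alive)), b0[alive], nb))
  emptied <- startCount > 0L & endCount == 0L
  if (any(emptied))
    warning(sum(emptied), " bin(s) lost all pixels during clipping; ",
            "flagged invalid")
  reportModel <- config@errorModel
  profile <- profileFromFrame(frame, bins, errorModel = reportModel,
                              inlier = inlier, varianceFloor = varianceFloor)
  new("ClipResult", profile = profile, inlierMask = inlier,
      iterations = iterations)
}
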