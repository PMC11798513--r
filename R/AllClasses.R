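#' @import methods
NULL

## Central S4 containers. Frames are plain numeric matrices (row = detector
## row); all per-pixel slots share the frame dimension. Radial bins are
## 1-based in R, with NA as the sentinel for masked / out-of-range pixels.

#' Detector geometry
#'
#' Fixed experimental geometry of a single-module area detector: frame shape,
#' pixel pitch and beam center. The beam center is given in fractional pixel
#' coordinates (0-based; a pixel's center sits at integer coordinates) and may
#' lie outside the frame. Sample-detector distance and wavelength are optional
#' and only needed for the q/d-spacing conversion helper.
#'
#' @slot nrow,ncol integer, frame shape in pixels.
#' @slot pixelSize numeric, pixel pitch in metres (use 1 for pixel units).
#' @slot beamCenter numeric(2), beam center as (row, col), 0-based fractional.
#' @slot distance numeric, sample-detector distance in metres (NA if unknown).
#' @slot wavelength numeric, wavelength in angstrom (NA if unknown).
#' @export
setClass("DetectorGeometry",
  representation(nrow = "integer", ncol = "integer", pixelSize = "numeric",
                 beamCenter = "numeric", distance = "numeric",
                 wavelength = "numeric"))

setValidity("DetectorGeometry", function(object) {
  msg <- character()
  if (length(object@nrow) != 1L || is.na(object@nrow) || object@nrow < 1L)
    msg <- c(msg, "'nrow' must be a single integer >= 1")
  if (length(object@ncol) != 1L || is.na(object@ncol) || object@ncol < 1L)
    msg <- c(msg, "'ncol' must be a single integer >= 1")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "'pixelSize' must be a single positive number")
  if (length(object@beamCenter) != 2L || any(!is.finite(object@beamCenter)))
    msg <- c(msg, "'beamCenter' must be two finite numbers (row, col)")
  if (length(msg)) msg else TRUE
})

#' @param nrow,ncol frame shape in pixels.
#' @param pixelSize pixel pitch in metres; 1 gives radii in pixel units.
#' @param beamCenter numeric(2), (row, col) of the beam center, 0-based
#'   fractional pixels. Defaults to the frame center.
#' @param distance optional sample-detector distance in metres.
#' @param wavelength optional wavelength in angstrom.
#' @return A `DetectorGeometry` object.
#' @examples
#' DetectorGeometry(64, 64, pixelSize = 75e-6)
#' @rdname DetectorGeometry-class
#' @export
DetectorGeometry <- function(nrow, ncol, pixelSize = 1,
                             beamCenter = c((nrow - 1) / 2, (ncol - 1) / 2),
                             distance = NA_real_, wavelength = NA_real_) {
  new("DetectorGeometry", nrow = as.integer(nrow), ncol = as.integer(ncol),
      pixelSize = as.numeric(pixelSize), beamCenter = as.numeric(beamCenter),
      distance = as.numeric(distance), wavelength = as.numeric(wavelength))
}

#' Sparse pixel-to-radial-bin assignment
#'
#' Look-up table mapping every pixel of a frame to one radial (azimuthal) bin,
#' the sparse-matrix form of azimuthal regrouping. Without pixel splitting each
#' pixel contributes to exactly one bin with coefficient 1; masked and
#' out-of-range pixels carry the NA sentinel.
#'
#' @slot nBins integer, number of radial bins.
#' @slot binEdges numeric(nBins + 1), strictly increasing bin edges in the
#'   radius unit of the radius map; bins are half-open `[lo, hi)`, last closed.
#' @slot pixelBin integer matrix (frame shape), 1-based bin index or NA.
#' @slot coefficients numeric matrix (frame shape), per-pixel coefficient in
#'   (0, 1]; all 1 in the no-splitting mode.
#' @slot binCount integer(nBins), pixels assigned to each bin.
#' @slot binRadius numeric(nBins), bin-center radii.
#' @export
setClass("BinAssignment",
  representation(nBins = "integer", binEdges = "numeric",
                 pixelBin = "matrix", coefficients = "matrix",
                 binCount = "integer", binRadius = "numeric"))

setValidity("BinAssignment", function(object) {
  msg <- character()
  if (length(object@binEdges) != object@nBins + 1L)
    msg <- c(msg, "'binEdges' must have length nBins + 1")
  if (any(diff(object@binEdges) <= 0))
    msg <- c(msg, "'binEdges' must be strictly increasing")
  if (!identical(dim(object@pixelBin), dim(object@coefficients)))
    msg <- c(msg, "'pixelBin' and 'coefficients' must share the frame shape")
  pb <- object@pixelBin
  if (any(pb < 1L | pb > object@nBins, na.rm = TRUE))
    msg <- c(msg, "bin indices must lie in [1, nBins] or be NA")
  cf <- object@coefficients[!is.na(pb)]
  if (any(cf <= 0 | cf > 1))
    msg <- c(msg, "coefficients of assigned pixels must lie in (0, 1]")
  if (sum(object@binCount) != sum(!is.na(pb)))
    msg <- c(msg, "binCount must partition the assigned pixels")
  if (length(msg)) msg else TRUE
})

#' Preprocessed detector frame
#'
#' Result of the pixel-wise corrections: the dark-subtracted signal, the
#' product of the normalization terms (flat field, solid angle, polarization,
#' efficiency, incoming flux), the per-pixel variance of the signal under the
#' chosen detector noise model, and the pixel mask. The corrected intensity is
#' `signal / norm`.
#'
#' @slot signal numeric matrix, raw minus dark (ADU).
#' @slot norm numeric matrix, strictly positive on unmasked pixels.
#' @slot variance numeric matrix, variance of `signal` (ADU^2).
#' @slot mask logical matrix, TRUE = masked (excluded).
#' @export
setClass("PreprocessedFrame",
  representation(signal = "matrix", norm = "matrix", variance = "matrix",
                 mask = "matrix"))

setValidity("PreprocessedFrame", function(object) {
  msg <- character()
  d <- dim(object@signal)
  if (!identical(d, dim(object@norm)) || !identical(d, dim(object@variance)) ||
      !identical(d, dim(object@mask)))
    msg <- c(msg, "all slots must share the frame shape")
  if (!is.logical(object@mask))
    msg <- c(msg, "'mask' must be logical")
  un <- !object@mask
  if (any(object@norm[un] <= 0))
    msg <- c(msg, "'norm' must be strictly positive on unmasked pixels")
  if (any(object@variance[un] < 0))
    msg <- c(msg, "'variance' must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Mergeable weighted statistics accumulator
#'
#' Single-pass accumulator of the weighted mean and variance of one radial
#' bin: the sum of weights, sum of squared weights, weighted sum of values and
#' weighted sum of squared deviations. Accumulators over disjoint pixel
#' partitions can be merged exactly, enabling parallel/chunked reduction.
#' The empty accumulator (all zero) is the identity element of [merge()].
#'
#' @slot omega numeric, sum of weights.
#' @slot omega2 numeric, sum of squared weights.
#' @slot V numeric, weighted sum of values.
#' @slot VV numeric, weighted sum of squared deviations from the running mean.
#' @slot count integer, number of accumulated values.
#' @export
setClass("WeightedAccumulator",
  representation(omega = "numeric", omega2 = "numeric", V = "numeric",
                 VV = "numeric", count = "integer"),
  prototype(omega = 0, omega2 = 0, V = 0, VV = 0, count = 0L))

#' @param omega,omega2,V,VV,count initial statistics; defaults give the empty
#'   accumulator.
#' @return A `WeightedAccumulator`.
#' @rdname WeightedAccumulator-class
#' @export
WeightedAccumulator <- function(omega = 0, omega2 = 0, V = 0, VV = 0,
                                count = 0L) {
  new("WeightedAccumulator", omega = as.numeric(omega),
      omega2 = as.numeric(omega2), V = as.numeric(V), VV = as.numeric(VV),
      count = as.integer(count))
}

#' Radial (azimuthal) intensity profile
#'
#' Per-bin weighted mean of the corrected intensity with two uncertainties:
#' `std`, the deviation of a single pixel value, and `sem`, the uncertainty of
#' the mean (sem = std / sqrt(N) for unit weights). Empty bins are flagged
#' invalid rather than zero-filled.
#'
#' @slot binRadius numeric, bin-center radii.
#' @slot mean,std,sem numeric per-bin statistics (NA on invalid bins).
#' @slot count integer, retained pixels per bin.
#' @slot valid logical, FALSE for bins with no contributing pixel.
#' @slot errorModel character, one of "poisson", "azimuthal", "hybrid".
#' @export
setClass("RadialProfile",
  representation(binRadius = "numeric", mean = "numeric", std = "numeric",
                 sem = "numeric", count = "integer", valid = "logical",
                 errorModel = "character"))

setValidity("RadialProfile", function(object) {
  n <- length(object@binRadius)
  if (any(lengths(list(object@mean, object@std, object@sem, object@count,
                       object@valid)) != n))
    return("all per-bin slots must have equal length")
  ok <- object@valid & object@count >= 1L
  if (any(object@std[ok] < -1e-12, na.rm = TRUE))
    return("'std' must be non-negative on valid bins")
  TRUE
})

#' Sigma-clipping configuration
#'
#' @slot snr numeric, rejection cutoff in sigma units; NA when `auto` is TRUE.
#' @slot auto logical, TRUE for the adaptive Chauvenet-variant cutoff
#'   [chauvenetCutoff()] recomputed from the shrinking bin population.
#' @slot maxIter integer, iteration cap (the loop exits early when no pixel is
#'   discarded).
#' @slot errorModel character; "hybrid" clips with the azimuthal (ring
#'   variance) model and reports Poisson uncertainties on the trimmed ensemble.
#' @export
setClass("ClipConfig",
  representation(snr = "numeric", auto = "logical", maxIter = "integer",
                 errorModel = "character"))

setValidity("ClipConfig", function(object) {
  msg <- character()
  if (!object@auto && (!is.finite(object@snr) || object@snr <= 0))
    msg <- c(msg, "fixed 'snr' must be a positive number")
  if (object@maxIter < 1L)
    msg <- c(msg, "'maxIter' must be >= 1")
  if (!object@errorModel %in% c("poisson", "azimuthal", "hybrid"))
    msg <- c(msg, "'errorModel' must be poisson, azimuthal or hybrid")
  if (length(msg)) msg else TRUE
})

#' @param snr rejection cutoff in sigma units, or `"auto"` for the adaptive
#'   Chauvenet-variant threshold.
#' @param maxIter maximum clipping iterations (early exit on convergence).
#' @param errorModel error model used for clipping and reporting.
#' @return A `ClipConfig`.
#' @examples
#' ClipConfig()                      # auto cutoff, hybrid model
#' ClipConfig(snr = 3, errorModel = "azimuthal")
#' @rdname ClipConfig-class
#' @export
ClipConfig <- function(snr = "auto", maxIter = 5L,
                       errorModel = c("hybrid", "poisson", "azimuthal")) {
  errorModel <- match.arg(errorModel)
  auto <- identical(snr, "auto")
  new("ClipConfig", snr = if (auto) NA_real_ else as.numeric(snr),
      auto = auto, maxIter = as.integer(maxIter), errorModel = errorModel)
}

#' Sigma-clipping result
#'
#' @slot profile [RadialProfile-class] of the post-clip background.
#' @slot inlierMask logical matrix, TRUE where the pixel survived clipping.
#' @slot iterations integer(nBins), iterations used until each bin stabilized.
#' @export
setClass("ClipResult",
  representation(profile = "RadialProfile", inlierMask = "matrix",
                 iterations = "integer"))

#' Sparse (lossily compressed) frame
#'
#' Retained pixels of one frame (those above background mean plus n sigma)
#' together with the radial background profile and enough geometry to rebuild
#' the radius map. Pixel indices are flat, 0-based, row-major (C order) and
#' strictly increasing; values are the corrected intensities, stored
#' losslessly.
#'
#' @slot pixelIndices integer, flat 0-based row-major indices.
#' @slot pixelValues numeric, corrected intensities of the retained pixels.
#' @slot backgroundMean,backgroundStd numeric(nBins), clipped profile.
#' @slot binEdges numeric(nBins + 1).
#' @slot dim integer(2) frame shape; @slot beamCenter numeric(2);
#'   @slot pixelSize numeric — geometry provenance.
#' @slot mask logical matrix, detector mask (shaded regions).
#' @slot frameId integer; @slot threshold numeric, the picking n.
#' @export
setClass("SparseFrame",
  representation(pixelIndices = "integer", pixelValues = "numeric",
                 backgroundMean = "numeric", backgroundStd = "numeric",
                 binEdges = "numeric", dim = "integer", beamCenter = "numeric",
                 pixelSize = "numeric", mask = "matrix", frameId = "integer",
                 threshold = "numeric"))

setValidity("SparseFrame", function(object) {
  msg <- character()
  idx <- object@pixelIndices
  if (length(idx) != length(object@pixelValues))
    msg <- c(msg, "indices and values must have equal length")
  if (length(idx) && (any(diff(idx) <= 0) || idx[1L] < 0L ||
                      idx[length(idx)] >= prod(object@dim)))
    msg <- c(msg, "indices must be strictly increasing, 0-based, in range")
  if (length(object@backgroundMean) != length(object@backgroundStd) ||
      length(object@binEdges) != length(object@backgroundMean) + 1L)
    msg <- c(msg, "background arrays must match the bin edges")
  if (length(msg)) msg else TRUE
})

#' Peak-finder configuration
#'
#' Defaults follow the published comparison settings: a 5x5 patch with a
#' minimum SNR of 3 and at least 4 patch pixels meeting the SNR condition
#' (the apex counts towards `minPixels`).
#'
#' @slot patchSize odd integer >= 3, local neighborhood side.
#' @slot minSnr numeric, SNR condition threshold in units of the ring sigma.
#' @slot minPixels integer, patch pixels that must pass the SNR condition.
#' @slot sigmaFloor numeric, lower bound on the per-ring sigma (a Poissonian
#'   detector baseline uses 1).
#' @export
setClass("PeakFinderConfig",
  representation(patchSize = "integer", minSnr = "numeric",
                 minPixels = "integer", sigmaFloor = "numeric"))

setValidity("PeakFinderConfig", function(object) {
  msg <- character()
  if (object@patchSize < 3L || object@patchSize %% 2L == 0L)
    msg <- c(msg, "'patchSize' must be an odd integer >= 3")
  if (object@minPixels < 1L || object@minPixels > object@patchSize^2)
    msg <- c(msg, "'minPixels' must lie in [1, patchSize^2]")
  if (!is.finite(object@minSnr))
    msg <- c(msg, "'minSnr' must be finite")
  if (length(msg)) msg else TRUE
})

#' @param patchSize odd patch side in pixels (3 or 5 typically).
#' @param minSnr minimum SNR for candidate and patch pixels.
#' @param minPixels patch pixels (apex included) that must pass the SNR test.
#' @param sigmaFloor lower bound applied to the ring sigma.
#' @return A `PeakFinderConfig`.
#' @rdname PeakFinderConfig-class
#' @export
PeakFinderConfig <- function(patchSize = 5L, minSnr = 3, minPixels = 4L,
                             sigmaFloor = 0) {
  new("PeakFinderConfig", patchSize = as.integer(patchSize),
      minSnr = as.numeric(minSnr), minPixels = as.integer(minPixels),
      sigmaFloor = as.numeric(sigmaFloor))
}

#' Per-frame peak list
#'
#' @slot frameId integer.
#' @slot peaks data.frame with one row per peak: `row`, `col` (0-based
#'   fractional centroid), `intensity` (background-subtracted sum), `sigma`
#'   (propagated deviation of the sum), `snr` (apex SNR), `nPixels`.
#' @export
setClass("PeakList",
  representation(frameId = "integer", peaks = "data.frame"))

#' Synthetic-frame simulation parameters
#'
#' Describes the data regime the separation targets: a smooth isotropic radial
#' background (constant plus two radial Gaussians, in expected counts) under
#' Poisson noise, sparse 2D-Gaussian Bragg peaks whose apex amplitude is set
#' from a target SNR against the local Poisson sigma, and masked gaps.
#'
#' @slot geometry [DetectorGeometry-class].
#' @slot background numeric named vector: `const`, `amp1`, `sigma1` (Gaussian
#'   centered at r = 0), `amp2`, `mu2`, `sigma2` (diffuse ring); units of
#'   expected counts, radii in the geometry's radius unit.
#' @slot nPeaks integer peaks per hit frame.
#' @slot peakSigma numeric, peak width in pixels.
#' @slot peakSnrRange numeric(2), apex SNR drawn uniformly from this range.
#' @slot maskFraction numeric in [0, 1), fraction of pixels masked as gaps.
#' @slot seed integer, makes generation reproducible.
#' @export
setClass("SimulationSpec",
  representation(geometry = "DetectorGeometry", background = "numeric",
                 nPeaks = "integer", peakSigma = "numeric",
                 peakSnrRange = "numeric", maskFraction = "numeric",
                 seed = "integer"))

setValidity("SimulationSpec", function(object) {
  msg <- character()
  need <- c("const", "amp1", "sigma1", "amp2", "mu2", "sigma2")
  if (!all(need %in% names(object@background)))
    msg <- c(msg, paste("background must name", paste(need, collapse = ", ")))
  else if (any(object@background[c("const", "amp1", "amp2")] < 0))
    msg <- c(msg, "background amplitudes must be non-negative")
  if (object@maskFraction < 0 || object@maskFraction >= 1)
    msg <- c(msg, "'maskFraction' must lie in [0, 1)")
  if (length(object@peakSnrRange) != 2L ||
      any(object@peakSnrRange <= 0) || diff(object@peakSnrRange) < 0)
    msg <- c(msg, "'peakSnrRange' must be an increasing positive pair")
  if (object@peakSigma <= 0) msg <- c(msg, "'peakSigma' must be positive")
  if (length(msg)) msg else TRUE
})
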