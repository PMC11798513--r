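#' Bin accessors
#'
#' Number of bins, edges and bin-center radii of a [BinAssignment-class] or
#' [RadialProfile-class].
#'
#' @param x a `BinAssignment` or `RadialProfile`.
#' @return `nBins()` an integer; `binEdges()` a numeric vector of length
#'   `nBins(x) + 1`; `binRadius()` the bin-center radii.
#' @name nBins
NULL

#' @rdname nBins
#' @export
setMethod("nBins", "BinAssignment", function(x) x@nBins)
#' @rdname nBins
#' @export
setMethod("nBins", "RadialProfile", function(x) length(x@binRadius))
#' @rdname nBins
#' @export
setMethod("binEdges", "BinAssignment", function(x) x@binEdges)
#' @rdname nBins
#' @export
setMethod("binRadius", "BinAssignment", function(x) x@binRadius)
#' @rdname nBins
#' @export
setMethod("binRadius", "RadialProfile", function(x) x@binRadius)

#' Frame accessors
#'
#' @param x a [PreprocessedFrame-class].
#' @return Matrices of the frame shape; `correctedIntensity()` is
#'   `signal / norm`.
#' @name frameData
NULL

#' @rdname frameData
#' @export
setMethod("signalData", "PreprocessedFrame", function(x) x@signal)
#' @rdname frameData
#' @export
setMethod("normData", "PreprocessedFrame", function(x) x@norm)
#' @rdname frameData
#' @export
setMethod("pixelMask", "PreprocessedFrame", function(x) x@mask)
#' @rdname frameData
#' @export
setMethod("correctedIntensity", "PreprocessedFrame",
          function(x) x@signal / x@norm)

#' Radial profile accessors
#'
#' @param x a [RadialProfile-class].
#' @return Numeric per-bin vectors (NA on invalid bins); `validBins()` is
#'   logical.
#' @name profileAccessors
NULL

#' @rdname profileAccessors
#' @export
setMethod("profileMean", "RadialProfile", function(x) x@mean)
#' @rdname profileAccessors
#' @export
setMethod("profileStd", "RadialProfile", function(x) x@std)
#' @rdname profileAccessors
#' @export
setMethod("profileSem", "RadialProfile", function(x) x@sem)
#' @rdname profileAccessors
#' @export
setMethod("validBins", "RadialProfile", function(x) x@valid)

#' @export
#' @describeIn profileAccessors profile as a data.frame with columns
#'   `radius`, `mean`, `std`, `sem`, `count`, `valid`.
setMethod("as.data.frame", "RadialProfile", function(x, ...) {
  data.frame(radius = x@binRadius, mean = x@mean, std = x@std, sem = x@sem,
             count = x@count, valid = x@valid)
})

#' Clip result accessors
#'
#' @param x a [ClipResult-class].
#' @return `clipProfile()` the post-clip [RadialProfile-class];
#'   `inlierMask()` a logical matrix, TRUE where the pixel survived clipping.
#' @name clipAccessors
NULL

#' @rdname clipAccessors
#' @export
setMethod("clipProfile", "ClipResult", function(x) x@profile)
#' @rdname clipAccessors
#' @export
setMethod("inlierMask", "ClipResult", function(x) x@inlierMask)

#' Peak list accessors
#'
#' @param x a [PeakList-class].
#' @return `peakTable()` the per-peak data.frame; `nPeaks()` the peak count.
#' @name peakAccessors
NULL

#' @rdname peakAccessors
#' @export
setMethod("peakTable", "PeakList", function(x) x@peaks)
#' @rdname peakAccessors
#' @export
setMethod("nPeaks", "PeakList", function(x) nrow(x@peaks))

setMethod("show", "DetectorGeometry", function(object) {
  cat(sprintf("DetectorGeometry: %d x %d px, pitch %g m, beam center (%g, %g)\n",
              object@nrow, object@ncol, object@pixelSize,
              object@beamCenter[1L], object@beamCenter[2L]))
  if (is.finite(object@distance))
    cat(sprintf("  distance %g m, wavelength %g A\n", object@distance,
                object@wavelength))
})

setMethod("show", "BinAssignment", function(object) {
  cat(sprintf("BinAssignment: %d bins over [%g, %g], %d assigned / %d masked px\n",
              object@nBins, object@binEdges[1L],
              object@binEdges[length(object@binEdges)],
              sum(object@binCount), sum(is.na(object@pixelBin))))
})

setMethod("show", "PreprocessedFrame", function(object) {
  cat(sprintf("PreprocessedFrame: %d x %d px, %d masked\n",
              nrow(object@signal), ncol(object@signal), sum(object@mask)))
})

setMethod("show", "WeightedAccumulator", function(object) {
  cat(sprintf("WeightedAccumulator: n=%d, omega=%g, mean=%s, VV=%g\n",
              object@count, object@omega,
              if (object@omega > 0) format(object@V / object@omega) else "NA",
              object@VV))
})

setMethod("show", "RadialProfile", function(object) {
  cat(sprintf("RadialProfile (%s): %d bins, %d valid\n", object@errorModel,
              length(object@binRadius), sum(object@valid)))
})

setMethod("show", "ClipResult", function(object) {
  cat(sprintf("ClipResult: %d / %d pixels retained, max %d iterations\n",
              sum(object@inlierMask), length(object@inlierMask),
              max(object@iterations, 0L)))
  show(object@profile)
})

setMethod("show", "SparseFrame", function(object) {
  cat(sprintf("SparseFrame #%d: %d / %d px retained (%.3g%%), n=%g, %d bins\n",
              object@frameId, length(object@pixelIndices), prod(object@dim),
              100 * length(object@pixelIndices) / prod(object@dim),
              object@threshold, length(object@backgroundMean)))
})

setMethod("show", "PeakList", function(object) {
  cat(sprintf("PeakList frame #%d: %d peaks\n", object@frameId,
              nrow(object@peaks)))
})

#' @export
#' @describeIn peakAccessors peaks as a data.frame with a `frame` column.
setMethod("as.data.frame", "PeakList", function(x, ...) {
  cbind(frame = rep(x@frameId, nrow(x@peaks)), x@peaks)
})
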