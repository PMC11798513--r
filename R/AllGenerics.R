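#' Add one weighted observation to an accumulator
#'
#' @param acc a [WeightedAccumulator-class].
#' @param v numeric vector of values (corrected intensities).
#' @param omega numeric vector of positive weights, recycled against `v`.
#' @return The updated accumulator.
#' @seealso [merge,WeightedAccumulator,WeightedAccumulator-method]
#' @export
setGeneric("accumulate", function(acc, v, omega = 1) standardGeneric("accumulate"))

#' @rdname nBins
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @rdname nBins
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))

#' @rdname nBins
#' @export
setGeneric("binRadius", function(x) standardGeneric("binRadius"))

#' @rdname frameData
#' @export
setGeneric("signalData", function(x) standardGeneric("signalData"))

#' @rdname frameData
#' @export
setGeneric("normData", function(x) standardGeneric("normData"))

#' @rdname frameData
#' @export
setGeneric("pixelMask", function(x) standardGeneric("pixelMask"))

#' @rdname frameData
#' @export
setGeneric("correctedIntensity", function(x) standardGeneric("correctedIntensity"))

#' @rdname profileAccessors
#' @export
setGeneric("profileMean", function(x) standardGeneric("profileMean"))

#' @rdname profileAccessors
#' @export
setGeneric("profileStd", function(x) standardGeneric("profileStd"))

#' @rdname profileAccessors
#' @export
setGeneric("profileSem", function(x) standardGeneric("profileSem"))

#' @rdname profileAccessors
#' @export
setGeneric("validBins", function(x) standardGeneric("validBins"))

#' @rdname clipAccessors
#' @export
setGeneric("clipProfile", function(x) standardGeneric("clipProfile"))

#' @rdname clipAccessors
#' @export
setGeneric("inlierMask", function(x) standardGeneric("inlierMask"))

#' @rdname peakAccessors
#' @export
setGeneric("peakTable", function(x) standardGeneric("peakTable"))

#' @rdname peakAccessors
#' @export
setGeneric("nPeaks", function(x) standardGeneric("nPeaks"))
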