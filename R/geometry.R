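#' Per-pixel radius map
#'
#' Distance of every pixel center from the beam center, in the unit of
#' `pixelSize` (metres, or pixels when `pixelSize = 1`). Pixel centers sit at
#' integer 0-based coordinates.
#'
#' @param geometry a [DetectorGeometry-class].
#' @return Numeric matrix of the frame shape with non-negative radii.
#' @examples
#' g <- DetectorGeometry(8, 8, beamCenter = c(0, 0))
#' buildRadiusMap(g)[4, 5]   # pixel (3, 4): the 3-4-5 triangle
#' @export
buildRadiusMap <- function(geometry) {
  stopifnot(is(geometry, "DetectorGeometry"))
  dr <- (seq_len(geometry@nrow) - 1) - geometry@beamCenter[1L]
  dc <- (seq_len(geometry@ncol) - 1) - geometry@beamCenter[2L]
  geometry@pixelSize * sqrt(outer(dr^2, dc^2, `+`))
}

#' Sparse pixel-to-bin assignment
#'
#' Bins the radius map into `nBins` equal-width radial bins spanning
#' `[0, max(radius)]` and records, per pixel, the bin it contributes to — the
#' look-up-table form of azimuthal regrouping. Bins are half-open `[lo, hi)`
#' with the last bin closed. No pixel splitting is performed: every unmasked
#' pixel falls in exactly one bin with coefficient 1.
#'
#' @param radiusMap numeric matrix from [buildRadiusMap()].
#' @param mask optional logical matrix, TRUE = excluded pixel.
#' @param nBins number of radial bins (>= 1). For 4M-class detectors 500 is a
#'   reasonable default; small test frames want proportionally fewer.
#' @return A [BinAssignment-class].
#' @examples
#' g <- DetectorGeometry(32, 32)
#' ba <- buildBinAssignment(buildRadiusMap(g), nBins = 10)
#' sum(ba@binCount) == 32 * 32
#' @export
buildBinAssignment <- function(radiusMap, mask = NULL, nBins = 500L) {
  stopifnot(is.matrix(radiusMap), nBins >= 1L)
  if (is.null(mask)) mask <- matrix(FALSE, nrow(radiusMap), ncol(radiusMap))
  stopifnot(identical(dim(mask), dim(radiusMap)))
  if (all(mask)) stop("all pixels are masked; cannot build a bin assignment")
  nBins <- as.integer(nBins)
  rmax <- max(radiusMap[!mask])
  edges <- seq(0, rmax, length.out = nBins + 1L)
  ## findInterval with rightmost.closed gives [lo, hi) bins, last closed
  bin <- findInterval(radiusMap, edges, rightmost.closed = TRUE)
  bin[bin < 1L | bin > nBins] <- NA_integer_
  bin[mask] <- NA_integer_
  bin <- matrix(as.integer(bin), nrow(radiusMap), ncol(radiusMap))
  counts <- tabulate(bin, nbins = nBins)
  new("BinAssignment", nBins = nBins, binEdges = edges, pixelBin = bin,
      coefficients = matrix(1, nrow(radiusMap), ncol(radiusMap)),
      binCount = as.integer(counts),
      binRadius = (edges[-1L] + edges[-(nBins + 1L)]) / 2)
}

#' Radius to momentum-transfer conversion
#'
#' Linear conversion helpers between detector radius and the modulus of the
#' scattering vector q = 4 pi sin(theta) / lambda (and d = 2 pi / q). Requires
#' the geometry's sample-detector distance and wavelength.
#'
#' @param radius numeric, radii in metres.
#' @param geometry a [DetectorGeometry-class] with `distance` and `wavelength`
#'   set.
#' @return `radiusToQ()` q in inverse angstrom; `qToResolution()` d-spacing in
#'   angstrom.
#' @export
radiusToQ <- function(radius, geometry) {
  stopifnot(is(geometry, "DetectorGeometry"))
  if (!is.finite(geometry@distance) || !is.finite(geometry@wavelength))
    stop("geometry needs 'distance' and 'wavelength' for q conversion")
  theta <- atan2(radius, geometry@distance) / 2
  4 * pi * sin(theta) / geometry@wavelength
}

#' @rdname radiusToQ
#' @param q numeric, scattering-vector moduli in inverse angstrom.
#' @export
qToResolution <- function(q) 2 * pi / q
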