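#' Pixel-wise correction set
#'
#' The corrections applied before any azimuthal statistic: the corrected
#' intensity of pixel i is
#' `(I_raw - I_dark) / (F * Omega * P * A * I0)`,
#' with F the flat field, Omega the relative solid angle, P the polarization
#' factor, A the apparent detector efficiency and I0 the incoming flux. Any
#' component may be omitted (`NULL`), in which case it is treated as 1 (dark
#' as 0). Components are per-pixel matrices except the scalar flux.
#'
#' @param dark per-pixel dark current (ADU), or NULL.
#' @param flat,solidAngle,polarization,efficiency per-pixel dimensionless
#'   normalization arrays, strictly positive where unmasked, or NULL.
#' @param flux scalar incoming-flux normalization, > 0.
#' @return A list of class `CorrectionSet`.
#' @seealso [solidAngleMap()], [polarizationMap()] for standard helpers.
#' @export
CorrectionSet <- function(dark = NULL, flat = NULL, solidAngle = NULL,
                          polarization = NULL, efficiency = NULL, flux = 1) {
  stopifnot(is.numeric(flux), length(flux) == 1L, flux > 0)
  structure(list(dark = dark, flat = flat, solidAngle = solidAngle,
                 polarization = polarization, efficiency = efficiency,
                 flux = flux),
            class = "CorrectionSet")
}

#' Apply pixel-wise corrections to a raw frame
#'
#' Produces the signal/normalization decomposition used by all downstream
#' statistics: `signal = raw - dark`, `norm = F * Omega * P * A * I0`. The
#' per-pixel variance of the signal follows the chosen detector noise model:
#' for a photon-counting (Poissonian) detector the counting statistics give
#' `var = max(signal, varianceFloor)` (lambda = mu = sigma^2), to which an
#' optional dark-noise variance map is added in quadrature; integrating
#' detectors with a calibrated noise map use `noiseModel = "variance-map"`.
#'
#' @param raw numeric matrix of raw intensities (ADU).
#' @param corrections a [CorrectionSet()].
#' @param mask logical matrix, TRUE = excluded; NULL for no mask.
#' @param noiseModel `"poisson"` or `"variance-map"`.
#' @param varianceMap per-pixel variance (ADU^2): the additive dark-noise term
#'   under `"poisson"`, the full variance under `"variance-map"`.
#' @param varianceFloor minimum Poisson variance so empty pixels keep a
#'   nonzero uncertainty (ADU^2).
#' @return A [PreprocessedFrame-class].
#' @examples
#' raw <- matrix(rpois(64, 100), 8, 8)
#' pf <- preprocessFrame(raw)
#' all(correctedIntensity(pf) == raw)
#' @export
preprocessFrame <- function(raw, corrections = CorrectionSet(), mask = NULL,
                            noiseModel = c("poisson", "variance-map"),
                            varianceMap = NULL, varianceFloor = 1) {
  noiseModel <- match.arg(noiseModel)
  stopifnot(is.matrix(raw))
  d <- dim(raw)
  if (is.null(mask)) mask <- matrix(FALSE, d[1L], d[2L])
  if (!identical(dim(mask), d)) stop("mask shape does not match the frame")
  comp <- function(x, default) {
    if (is.null(x)) return(matrix(default, d[1L], d[2L]))
    if (!identical(dim(x), d)) stop("correction array shape mismatch")
    x
  }
  dark <- comp(corrections$dark, 0)
  norm <- comp(corrections$flat, 1) * comp(corrections$solidAngle, 1) *
    comp(corrections$polarization, 1) * comp(corrections$efficiency, 1) *
    corrections$flux
  if (any(norm[!mask] <= 0))
    stop("non-positive normalization on an unmasked pixel")
  signal <- raw - dark
  variance <- switch(noiseModel,
    poisson = {
      v <- pmax(signal, varianceFloor)
      if (!is.null(varianceMap)) {
        if (!identical(dim(varianceMap), d))
          stop("variance map shape mismatch")
        v <- v + varianceMap    # dark noise superimposes quadratically
      }
      v
    },
    `variance-map` = {
      if (is.null(varianceMap)) stop("'variance-map' model needs a map")
      if (!identical(dim(varianceMap), d)) stop("variance map shape mismatch")
      varianceMap
    })
  new("PreprocessedFrame", signal = signal, norm = norm,
      variance = matrix(as.numeric(variance), d[1L], d[2L]), mask = mask)
}

#' Standard geometric correction helpers
#'
#' Convenience builders for the solid-angle and polarization normalization
#' arrays of [CorrectionSet()]. `solidAngleMap()` uses the flat-detector
#' cos^3(2theta) approximation of the relative solid angle subtended by each
#' pixel; `polarizationMap()` the textbook factor
#' `P = 1 - pf * sin^2(2theta) * cos^2(chi)` for polarization fraction `pf`
#' and azimuth chi measured from the polarization plane. Both require the
#' sample-detector distance; they are conveniences, not calibrations.
#'
#' @param geometry a [DetectorGeometry-class] with `distance` set.
#' @return Numeric matrix of the frame shape, normalized to 1 on the beam axis.
#' @export
solidAngleMap <- function(geometry) {
  if (!is.finite(geometry@distance))
    stop("geometry needs 'distance' for the solid-angle map")
  r <- buildRadiusMap(geometry)
  cos(atan2(r, geometry@distance))^3
}

#' @rdname solidAngleMap
#' @param polarizationFactor polarization fraction `pf` in [0, 1]
#'   (synchrotron beams are close to 1 in the orbit plane).
#' @export
polarizationMap <- function(geometry, polarizationFactor = 0.99) {
  if (!is.finite(geometry@distance))
    stop("geometry needs 'distance' for the polarization map")
  r <- buildRadiusMap(geometry)
  tth <- atan2(r, geometry@distance)
  dr <- (seq_len(geometry@nrow) - 1) - geometry@beamCenter[1L]
  dc <- (seq_len(geometry@ncol) - 1) - geometry@beamCenter[2L]
  chi <- atan2(outer(dr, rep(1, geometry@ncol)),
               outer(rep(1, geometry@nrow), dc))
  1 - polarizationFactor * sin(tth)^2 * cos(chi)^2
}
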