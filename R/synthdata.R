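#' Simulation parameters for synthetic diffraction frames
#'
#' Defaults describe a realistic desk-scale regime: a 256x256 detector, a
#' smooth isotropic background (forward-scattering Gaussian falling from 250
#' to a 50-count floor plus a diffuse amorphous ring at 55% of the maximum
#' radius), Poisson counting noise, and Bragg peaks of 1-pixel width whose
#' apex rises 10-50 Poisson sigmas above the local background. Background
#' radii scale with the geometry unless given explicitly.
#'
#' @param geometry a [DetectorGeometry-class].
#' @param background named numeric vector `const`, `amp1`, `sigma1`, `amp2`,
#'   `mu2`, `sigma2` (expected counts; radii in the geometry's radius unit).
#' @param nPeaks peaks per hit frame.
#' @param peakSigma Gaussian peak width (pixels).
#' @param peakSnrRange apex SNR range, drawn uniformly.
#' @param maskFraction fraction of rows masked as a detector gap.
#' @param seed integer seed; generation is bit-reproducible given the spec.
#' @return A [SimulationSpec-class].
#' @export
SimulationSpec <- function(geometry = DetectorGeometry(256L, 256L),
                           background = NULL, nPeaks = 50L, peakSigma = 1,
                           peakSnrRange = c(10, 50), maskFraction = 0.02,
                           seed = 1L) {
  rmax <- max(buildRadiusMap(geometry))
  if (is.null(background))
    background <- c(const = 50, amp1 = 200, sigma1 = 0.3 * rmax,
                    amp2 = 100, mu2 = 0.55 * rmax, sigma2 = 0.08 * rmax)
  new("SimulationSpec", geometry = geometry,
      background = background, nPeaks = as.integer(nPeaks),
      peakSigma = as.numeric(peakSigma),
      peakSnrRange = as.numeric(peakSnrRange),
      maskFraction = as.numeric(maskFraction), seed = as.integer(seed))
}

#' Analytic background of a simulation spec
#'
#' @param spec a [SimulationSpec-class].
#' @param r numeric radii.
#' @return Expected background counts at `r`.
#' @export
backgroundAt <- function(spec, r) {
  p <- spec@background
  p[["const"]] + p[["amp1"]] * exp(-r^2 / (2 * p[["sigma1"]]^2)) +
    p[["amp2"]] * exp(-(r - p[["mu2"]])^2 / (2 * p[["sigma2"]]^2))
}

## Rejection-sample fractional peak centers: inside the margin, pairwise
## spacing >= minSpacing, at least 3 px from any masked pixel.
.placePeaks <- function(nr, nc, n, mask, minSpacing = 15, margin = 12) {
  if (n == 0L) return(cbind(row = numeric(0), col = numeric(0)))
  rows <- numeric(n); cols <- numeric(n); placed <- 0L
  attempts <- 0L; maxAttempts <- 2000L * n
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > maxAttempts)
      stop("could not place ", n, " peaks under the spacing constraints; ",
           "reduce nPeaks or the frame coverage")
    r0 <- runif(1, margin, nr - 1 - margin)
    c0 <- runif(1, margin, nc - 1 - margin)
    ri <- round(r0) + 1L; ci <- round(c0) + 1L
    win <- mask[max(1L, ri - 3L):min(nr, ri + 3L),
                max(1L, ci - 3L):min(nc, ci + 3L)]
    if (any(win)) next
    if (placed > 0L &&
        min((rows[seq_len(placed)] - r0)^2 +
            (cols[seq_len(placed)] - c0)^2) < minSpacing^2) next
    placed <- placed + 1L
    rows[placed] <- r0; cols[placed] <- c0
  }
  cbind(row = rows, col = cols)
}

#' Generate synthetic diffraction frames with ground truth
#'
#' Draws `nFrames` frames from the spec's model: per pixel, Poisson counts of
#' the analytic radial background plus the injected 2D-Gaussian peaks. Peak
#' apex amplitude is `snr * sqrt(background)` so the recorded SNR is relative
#' to the local Poisson sigma. Frames flagged as non-hits receive no peaks
#' (the pure-background control for veto and false-positive tests). Masked
#' pixels are zeroed. Generation is fully determined by `spec@seed`.
#'
#' The ground-truth manifest records every injected peak (frame, fractional
#' 0-based center, apex SNR and amplitude) and the analytic background is
#' available through [backgroundAt()].
#'
#' @param spec a [SimulationSpec-class].
#' @param nFrames number of frames.
#' @param hit logical vector (recycled): does the frame contain peaks?
#' @return List with `frames` (list of integer-count matrices), `mask`
#'   (logical matrix), `peaks` (data.frame manifest), `radiusMap`, and `spec`.
#' @examples
#' sim <- simulateFrames(SimulationSpec(DetectorGeometry(128L, 128L),
#'                                      nPeaks = 5L, seed = 42L))
#' nrow(sim$peaks)
#' @export
simulateFrames <- function(spec, nFrames = 1L, hit = TRUE) {
  stopifnot(is(spec, "SimulationSpec"))
  validObject(spec)
  hit <- rep_len(hit, nFrames)
  g <- spec@geometry
  nr <- g@nrow; nc <- g@ncol
  r <- buildRadiusMap(g)
  lambda0 <- backgroundAt(spec, r)
  withSeed(spec@seed, {
    mask <- matrix(FALSE, nr, nc)
    if (spec@maskFraction > 0) {
      h <- max(1L, round(spec@maskFraction * nr))
      top <- sample.int(nr - h + 1L, 1L)      # horizontal gap, module-style
      mask[top:(top + h - 1L), ] <- TRUE
    }
    frames <- vector("list", nFrames)
    manifest <- vector("list", nFrames)
    halfWin <- ceiling(4 * spec@peakSigma)
    for (f in seq_len(nFrames)) {
      lambda <- lambda0
      if (hit[f] && spec@nPeaks > 0L) {
        ctr <- .placePeaks(nr, nc, spec@nPeaks, mask,
                           minSpacing = 15, margin = halfWin + 8)
        snr <- runif(spec@nPeaks, spec@peakSnrRange[1L], spec@peakSnrRange[2L])
        amp <- numeric(spec@nPeaks)
        for (p in seq_len(spec@nPeaks)) {
          r0 <- ctr[p, 1L]; c0 <- ctr[p, 2L]
          amp[p] <- snr[p] * sqrt(backgroundAt(spec, r[round(r0) + 1L,
                                                       round(c0) + 1L]))
          rows <- max(1L, round(r0) + 1L - halfWin):
                  min(nr, round(r0) + 1L + halfWin)
          cols <- max(1L, round(c0) + 1L - halfWin):
                  min(nc, round(c0) + 1L + halfWin)
          d2 <- outer(((rows - 1L) - r0)^2, ((cols - 1L) - c0)^2, `+`)
          lambda[rows, cols] <- lambda[rows, cols] +
            amp[p] * exp(-d2 / (2 * spec@peakSigma^2))
        }
        manifest[[f]] <- data.frame(frame = f - 1L, row = ctr[, 1L],
                                    col = ctr[, 2L], snr = snr,
                                    amplitude = amp)
      } else {
        manifest[[f]] <- data.frame(frame = integer(0), row = numeric(0),
                                    col = numeric(0), snr = numeric(0),
                                    amplitude = numeric(0))
      }
      fr <- matrix(rpois(nr * nc, lambda), nr, nc)
      fr[mask] <- 0L
      frames[[f]] <- fr
    }
    list(frames = frames, mask = mask, peaks = do.call(rbind, manifest),
         radiusMap = r, spec = spec)
  })
}
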