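## Weighted azimuthal statistics.
##
## Pixel i contributes value v_i = signal_i / norm_i with weight
## omega_i = c_i * norm_i. Per radial bin the accumulated quantities are
##   Omega  = sum omega_i          Omega2 = sum omega_i^2
##   V      = sum omega_i * v_i    VV     = sum omega_i * (v_i - V/Omega)^2
## giving mean = V / Omega and, under the azimuthal (ring-variance) error
## model, std^2 = VV / Omega (weighted population variance of a pixel value)
## and sem^2 = VV * Omega2 / Omega^3 (Kish effective sample size
## N_eff = Omega^2 / Omega2 generalizing sem = std / sqrt(N)).
## Under the Poisson model sem^2 = sum c_i^2 sigma_i^2 / Omega^2 with
## sigma_i^2 the detector variance of signal_i, and std = sem * sqrt(N_eff).

#' @rdname accumulate
#' @details The streaming update adds one member at a time:
#'   `VV <- VV + omega * (v - V_old/Omega_old) * (v - V_new/Omega_new)`,
#'   with the first member contributing zero deviation. All arithmetic is in
#'   double precision.
#' @examples
#' acc <- accumulate(WeightedAccumulator(), c(1, 199))
#' accumulatorStats(acc)$mean    # 100
#' accumulatorStats(acc)$std     # 99: each pixel is 1 sigma from the mean
#' @export
setMethod("accumulate", "WeightedAccumulator", function(acc, v, omega = 1) {
  v <- as.numeric(v)
  omega <- rep_len(as.numeric(omega), length(v))
  if (any(omega <= 0)) stop("weights must be strictly positive")
  O <- acc@omega; O2 <- acc@omega2; V <- acc@V; VV <- acc@VV
  for (i in seq_along(v)) {
    w <- omega[i]; x <- v[i]
    Onew <- O + w
    Vnew <- V + w * x
    if (O > 0) VV <- VV + w * (x - V / O) * (x - Vnew / Onew)
    O <- Onew; V <- Vnew; O2 <- O2 + w * w
  }
  new("WeightedAccumulator", omega = O, omega2 = O2, V = V, VV = max(VV, 0),
      count = acc@count + length(v))
})

#' Merge two partial accumulators
#'
#' Exact union of the weighted statistics of two disjoint pixel partitions:
#' `Omega`, `Omega2`, `V` and the count add, and the deviation numerator
#' gains a between-partition term,
#' `VV_AB = VV_A + VV_B + (Omega_A * Omega_B / Omega_AB) *
#' (V_A/Omega_A - V_B/Omega_B)^2`. The empty accumulator is the identity;
#' merging is commutative and associative (up to rounding), which is what
#' permits chunked and parallel reduction.
#'
#' @param x,y [WeightedAccumulator-class] objects over disjoint pixel sets.
#' @param ... ignored.
#' @return The merged accumulator.
#' @export
setMethod("merge", signature("WeightedAccumulator", "WeightedAccumulator"),
          function(x, y, ...) {
  if (x@count == 0L) return(y)
  if (y@count == 0L) return(x)
  O <- x@omega + y@omega
  delta <- x@V / x@omega - y@V / y@omega
  VV <- x@VV + y@VV + (x@omega * y@omega / O) * delta * delta
  new("WeightedAccumulator", omega = O, omega2 = x@omega2 + y@omega2,
      V = x@V + y@V, VV = VV, count = x@count + y@count)
})

#' Summary statistics of an accumulator
#'
#' @param acc a [WeightedAccumulator-class].
#' @return List with `mean`, `std` (azimuthal pixel-level deviation,
#'   `sqrt(VV/Omega)`), `sem` (`sqrt(VV * Omega2 / Omega^3)`), `neff` (Kish
#'   effective sample size) and `count`. All NA for an empty accumulator.
#' @export
accumulatorStats <- function(acc) {
  stopifnot(is(acc, "WeightedAccumulator"))
  if (acc@count == 0L || acc@omega <= 0)
    return(list(mean = NA_real_, std = NA_real_, sem = NA_real_,
                neff = NA_real_, count = acc@count))
  list(mean = acc@V / acc@omega,
       std = sqrt(max(acc@VV, 0) / acc@omega),
       sem = sqrt(max(acc@VV, 0) * acc@omega2 / acc@omega^3),
       neff = acc@omega^2 / acc@omega2,
       count = acc@count)
}

## Per-bin sums of x grouped by bin index b (NA-free), length nBins.
.binsum <- function(x, b, nBins) {
  out <- numeric(nBins)
  if (length(x)) {
    s <- rowsum(x, b, reorder = FALSE)
    out[as.integer(rownames(s))] <- s
  }
  out
}

#' Radial profile of a preprocessed frame
#'
#' Weighted azimuthal mean and uncertainties per radial bin, under one of
#' three error models:
#' \describe{
#'   \item{azimuthal}{pixel-level deviation measured from the spread of
#'     intensities within the ring (`std^2 = VV/Omega`); robust to detectors
#'     without a known noise law, but noisier from bin to bin.}
#'   \item{poisson}{propagates the per-pixel detector variance of the frame;
#'     `sem^2 = sum c_i^2 sigma_i^2 / Omega^2` (the coefficient is squared
#'     when propagating variance) and `std = sem * sqrt(N_eff)`.}
#'   \item{hybrid}{Poisson uncertainties computed from the mean-based rate of
#'     the ensemble (`sigma_i^2 = max(mean * norm_i, varianceFloor)`); this is
#'     the reporting model used after hybrid sigma clipping.}
#' }
#' Bins without any contributing pixel are flagged invalid (`NA` statistics),
#' never dropped or zero-filled.
#'
#' @param frame a [PreprocessedFrame-class].
#' @param bins a [BinAssignment-class] on the same frame shape.
#' @param errorModel `"azimuthal"`, `"poisson"` or `"hybrid"`.
#' @param inlier optional logical matrix restricting the statistic to a pixel
#'   subset (as produced by [sigmaClip()]).
#' @param varianceFloor minimum per-pixel variance under the hybrid model.
#' @return A [RadialProfile-class].
#' @export
profileFromFrame <- function(frame, bins,
                             errorModel = c("azimuthal", "poisson", "hybrid"),
                             inlier = NULL, varianceFloor = 1) {
  errorModel <- match.arg(errorModel)
  stopifnot(is(frame, "PreprocessedFrame"), is(bins, "BinAssignment"))
  if (!identical(dim(frame@signal), dim(bins@pixelBin)))
    stop("bin assignment does not match the frame shape")
  keep <- !frame@mask & !is.na(bins@pixelBin)
  if (!is.null(inlier)) keep <- keep & inlier
  idx <- which(keep)
  b <- bins@pixelBin[idx]
  nb <- bins@nBins
  cf <- bins@coefficients[idx]
  nrm <- frame@norm[idx]
  v <- frame@signal[idx] / nrm
  w <- cf * nrm
  O <- .binsum(w, b, nb)
  O2 <- .binsum(w * w, b, nb)
  V <- .binsum(w * v, b, nb)
  count <- as.integer(.binsum(rep(1, length(idx)), b, nb))
  valid <- count >= 1L & O > 0
  mu <- ifelse(valid, V / O, NA_real_)
  if (errorModel == "azimuthal") {
    dev <- v - mu[b]
    VV <- .binsum(w * dev * dev, b, nb)
    std <- ifelse(valid, sqrt(pmax(VV, 0) / O), NA_real_)
    sem <- ifelse(valid, sqrt(pmax(VV, 0) * O2 / O^3), NA_real_)
  } else {
    sig2 <- if (errorModel == "poisson") frame@variance[idx]
            else pmax(mu[b] * nrm, varianceFloor)
    S <- .binsum(cf * cf * sig2, b, nb)
    sem <- ifelse(valid, sqrt(S) / O, NA_real_)
    neff <- ifelse(valid, O^2 / O2, NA_real_)
    std <- sem * sqrt(neff)
  }
  new("RadialProfile", binRadius = bins@binRadius, mean = mu, std = std,
      sem = sem, count = count, valid = valid, errorModel = errorModel)
}

#' Write a profile as 3-column text
#'
#' Plain whitespace-separated columns `radius mean std` with a `#` header,
#' invalid bins written as NaN.
#'
#' @param profile a [RadialProfile-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeProfileTxt <- function(profile, path) {
  stopifnot(is(profile, "RadialProfile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# radius mean std (error model: %s)",
                     profile@errorModel), con)
  write.table(
    data.frame(radius = profile@binRadius,
               mean = ifelse(profile@valid, profile@mean, NaN),
               std = ifelse(profile@valid, profile@std, NaN)),
    con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
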