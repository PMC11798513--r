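# Noiseless scene with one or more injected Gaussian peaks on a flat
# background, analysed with a fixed variance map so the SNR scale is exact.
injectedScene <- function(centers, amp = 200, base = 100, sigma = 1,
                          n = 96L, noiseSd = 10) {
  g <- DetectorGeometry(n, n)
  fr <- matrix(base, n, n)
  for (k in seq_len(nrow(centers))) {
    r0 <- centers[k, 1]; c0 <- centers[k, 2]
    d2 <- outer(((1:n) - 1 - r0)^2, ((1:n) - 1 - c0)^2, `+`)
    fr <- fr + amp * exp(-d2 / (2 * sigma^2))
  }
  pf <- preprocessFrame(fr, noiseModel = "variance-map",
                        varianceMap = matrix(noiseSd^2, n, n))
  ba <- buildBinAssignment(buildRadiusMap(g), nBins = 1L)
  # flat background: a single global bin with the known sigma
  cr <- sigmaClip(pf, ba, ClipConfig(snr = 50, errorModel = "poisson",
                                     maxIter = 1L))
  list(pf = pf, ba = ba, cr = cr)
}

test_that("a featureless frame yields zero peaks", {
  ba <- buildBinAssignment(buildRadiusMap(DetectorGeometry(64L, 64L)),
                           nBins = 8L)
  pf <- preprocessFrame(matrix(100, 64, 64))
  cr <- sigmaClip(pf, ba, ClipConfig(snr = 3, errorModel = "poisson"))
  pl <- findPeaks(pf, cr, ba, PeakFinderConfig())
  expect_identical(nPeaks(pl), 0L)
})

test_that("a single injected Gaussian is found with an accurate centroid", {
  sc <- injectedScene(cbind(40.3, 55.7), amp = 200, noiseSd = 10)
  pl <- findPeaks(sc$pf, sc$cr, sc$ba,
                  PeakFinderConfig(patchSize = 5L, minSnr = 3, minPixels = 4L))
  expect_identical(nPeaks(pl), 1L)
  pt <- peakTable(pl)
  expect_lt(abs(pt$row - 40.3), 0.3)
  expect_lt(abs(pt$col - 55.7), 0.3)
  expect_gte(pt$nPixels, 4L)
  expect_gt(pt$intensity, 0)
  expect_gt(pt$sigma, 0)
  # brute-force oracle: the apex must be the patch maximum
  v <- correctedIntensity(sc$pf)
  apex <- which(v == max(v), arr.ind = TRUE)
  expect_lt(abs(pt$row - (apex[1] - 1)), 1)
})

test_that("centroids are translation equivariant", {
  base <- c(30.2, 45.6)
  pl0 <- findPeaks(injectedScene(rbind(base))$pf,
                   injectedScene(rbind(base))$cr,
                   injectedScene(rbind(base))$ba, PeakFinderConfig())
  for (shift in list(c(7, 0), c(0, -9), c(11, 13))) {
    sc <- injectedScene(rbind(base + shift))
    pl <- findPeaks(sc$pf, sc$cr, sc$ba, PeakFinderConfig())
    expect_identical(nPeaks(pl), 1L)
    d <- unlist(peakTable(pl)[1, c("row", "col")]) -
      unlist(peakTable(pl0)[1, c("row", "col")])
    expect_lt(max(abs(d - shift)), 0.05)
  }
})

test_that("many injected peaks are recovered one-to-one on a noisy frame", {
  sc <- smallScene(n = 256L, nPeaks = 40L, seed = 201L, nBins = 48L)
  pf <- preprocessFrame(sc$sim$frames[[1]], mask = sc$sim$mask)
  cr <- sigmaClip(pf, sc$bins)
  pl <- findPeaks(pf, cr, sc$bins, PeakFinderConfig())
  pt <- peakTable(pl)
  truth <- sc$sim$peaks
  expect_identical(nPeaks(pl), 40L)
  d <- vapply(seq_len(nrow(truth)), function(j)
    sqrt(min((pt$row - truth$row[j])^2 + (pt$col - truth$col[j])^2)),
    numeric(1))
  expect_true(all(d < 1))
  # and the matched pure-background frame stays clean at SNR 5
  simBg <- simulateFrames(sc$spec, nFrames = 1L, hit = FALSE)
  pfBg <- preprocessFrame(simBg$frames[[1]], mask = simBg$mask)
  crBg <- sigmaClip(pfBg, sc$bins)
  expect_identical(nPeaks(findPeaks(pfBg, crBg, sc$bins,
                                    PeakFinderConfig(minSnr = 5))), 0L)
})

test_that("raising minSnr or minPixels never increases the peak count", {
  sc <- smallScene(n = 192L, nPeaks = 20L, seed = 211L, nBins = 40L)
  pf <- preprocessFrame(sc$sim$frames[[1]], mask = sc$sim$mask)
  cr <- sigmaClip(pf, sc$bins)
  countAt <- function(minSnr, minPixels)
    nPeaks(findPeaks(pf, cr, sc$bins,
                     PeakFinderConfig(minSnr = minSnr,
                                      minPixels = as.integer(minPixels))))
  snrCounts <- vapply(c(2, 3, 4, 6), countAt, integer(1), minPixels = 4)
  expect_true(all(diff(snrCounts) <= 0))
  pxCounts <- vapply(c(1, 4, 9, 16), function(p) countAt(3, p), integer(1))
  expect_true(all(diff(pxCounts) <= 0))
})

test_that("false positives on pure noise are controlled at SNR 5", {
  gf <- gaussianFrame(256, sigma = 10, seed = 31)
  ba <- buildBinAssignment(gf$radius, nBins = 48L)
  cr <- sigmaClip(gf$frame, ba, ClipConfig(snr = 5, errorModel = "azimuthal",
                                           maxIter = 2L))
  pl <- findPeaks(gf$frame, cr, ba, PeakFinderConfig(minSnr = 5))
  # expected candidate apexes ~ Q(5) * npix ~ 0.02; registered peaks (which
  # additionally need minPixels neighbors over SNR) must stay at ~zero
  expect_lte(nPeaks(pl), 1L)
})

test_that("ring statistics beat square-window statistics under steep radial structure", {
  # a sharp diffuse ring near the beam center: per-ring sigma tracks it,
  # square-neighborhood statistics are biased by it
  set.seed(123)
  n <- 128L
  g <- DetectorGeometry(n, n)
  r <- buildRadiusMap(g)
  lam <- 50 + 4000 * exp(-(r - 20)^2 / (2 * 2^2))
  fr <- matrix(rpois(n * n, lam), n, n)
  pf <- preprocessFrame(fr)
  ba <- buildBinAssignment(r, nBins = 96L)
  cr <- sigmaClip(pf, ba, ClipConfig(errorModel = "azimuthal"))
  pt <- peakTable(findPeaks(pf, cr, ba,
                            PeakFinderConfig(minSnr = 2, minPixels = 4L)))
  ringFalse <- sum(sqrt((pt$row - 63.5)^2 + (pt$col - 63.5)^2) < 35)
  # baseline oracle: local mean/sd over a square neighborhood, sigma floor 1
  w <- 10L
  lm <- matrix(0, n, n); ls <- matrix(1, n, n)
  for (i in 1:n) for (j in 1:n) {
    rows <- max(1, i - w):min(n, i + w); cols <- max(1, j - w):min(n, j + w)
    x <- fr[rows, cols]
    lm[i, j] <- mean(x); ls[i, j] <- sd(x)
  }
  snrL <- (fr - lm) / pmax(ls, 1)
  cand <- which(snrL >= 2, arr.ind = TRUE)
  baseFalse <- 0L
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    rows <- max(1, i - 2):min(n, i + 2); cols <- max(1, j - 2):min(n, j + 2)
    if (any(fr[rows, cols] > fr[i, j])) next
    if (sum(snrL[rows, cols] >= 2) < 4) next
    if (sqrt((i - 1 - 63.5)^2 + (j - 1 - 63.5)^2) < 35)
      baseFalse <- baseFalse + 1L
  }
  expect_lt(ringFalse, baseFalse)
})

test_that("CXI files round trip with the padded-row contract", {
  sc <- smallScene(n = 128L, nPeaks = 6L, seed = 221L, nFrames = 3L,
                   hit = c(TRUE, FALSE, TRUE))
  pls <- lapply(seq_len(3), function(i) {
    pf <- preprocessFrame(sc$sim$frames[[i]], mask = sc$sim$mask)
    findPeaks(pf, sigmaClip(pf, sc$bins), sc$bins, PeakFinderConfig(),
              frameId = i - 1L)
  })
  path <- withr::local_tempfile(fileext = ".cxi")
  writeCxi(pls, path, maxPeaks = 32L)
  counts <- as.integer(rhdf5::h5read(path, "entry_1/result_1/nPeaks"))
  expect_identical(counts, vapply(pls, nPeaks, integer(1)))
  expect_identical(counts[2], 0L)                   # non-hit: padded zeros
  x <- rhdf5::h5read(path, "entry_1/result_1/peakXPosRaw")
  expect_identical(dim(x), c(32L, 3L))              # on disk: (3, 32) C-order
  expect_true(all(x[(counts[1] + 1):32, 1] == 0))
  back <- readCxi(path)
  for (i in c(1L, 3L)) {
    expect_equal(peakTable(back[[i]])$row, peakTable(pls[[i]])$row)
    expect_equal(peakTable(back[[i]])$col, peakTable(pls[[i]])$col)
    expect_equal(peakTable(back[[i]])$intensity, peakTable(pls[[i]])$intensity)
    expect_equal(peakTable(back[[i]])$snr, peakTable(pls[[i]])$snr)
  }
  expect_identical(nPeaks(back[[2]]), 0L)
  # no two peaks share an apex: row-major candidate order makes them unique
  expect_false(any(duplicated(round(peakTable(pls[[1]])[c("row", "col")]))))
})

test_that("the veto keeps frames by peak count with a >= threshold", {
  mk <- function(k) new("PeakList", frameId = 0L,
                        peaks = data.frame(row = numeric(k), col = numeric(k),
                                           intensity = numeric(k),
                                           sigma = numeric(k),
                                           snr = numeric(k),
                                           nPixels = integer(k)))
  expect_true(vetoFrame(mk(0), 0))        # threshold 0 keeps everything
  expect_false(vetoFrame(mk(19), 20))     # 19 peaks < 20: discarded
  expect_true(vetoFrame(mk(20), 20))      # exactly 20: kept
})

test_that("the veto separates hit from non-hit frames in a synthetic stream", {
  nF <- 30L
  hits <- rep(FALSE, nF); hits[seq(1, nF, by = 3)] <- TRUE  # 10 hits
  sc <- smallScene(n = 128L, nPeaks = 12L, seed = 231L, nFrames = nF,
                   hit = hits)
  kept <- vapply(seq_len(nF), function(i) {
    pf <- preprocessFrame(sc$sim$frames[[i]], mask = sc$sim$mask)
    pl <- findPeaks(pf, sigmaClip(pf, sc$bins), sc$bins,
                    PeakFinderConfig(minSnr = 4))
    vetoFrame(pl, 6)
  }, logical(1))
  expect_identical(kept, hits)
})
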