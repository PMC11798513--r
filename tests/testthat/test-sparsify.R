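test_that("analytic keep fraction is the normal upper tail", {
  expect_equal(theoreticalKeepFraction(0), 0.5)
  expect_equal(signif(theoreticalKeepFraction(1), 2), 0.16)
  expect_equal(signif(theoreticalKeepFraction(2), 2), 0.023)
  expect_equal(signif(theoreticalKeepFraction(3), 2), 0.0013)
  # independent oracle: numerical integration of the normal density
  q15 <- integrate(dnorm, 1.5, Inf)$value
  expect_equal(theoreticalKeepFraction(1.5), q15, tolerance = 1e-8)
  n <- seq(0, 4, by = 0.25)
  expect_true(all(diff(theoreticalKeepFraction(n)) < 0))
})

test_that("theoretical compression follows the two-numbers-per-pixel model", {
  expect_equal(round(theoreticalCompressionRatio(2)), 22)
  expect_gte(theoreticalCompressionRatio(1.5), 6.4)
  n <- seq(0.5, 4, by = 0.5)
  expect_true(all(diff(theoreticalCompressionRatio(n)) > 0))
  expect_error(theoreticalCompressionRatio(0))
})

test_that("picking respects the mean + n sigma rule exactly", {
  gf <- gaussianFrame(96, sigma = 10, seed = 8)
  ba <- buildBinAssignment(gf$radius, nBins = 16L)
  cr <- sigmaClip(gf$frame, ba, ClipConfig(snr = 5, errorModel = "azimuthal",
                                           maxIter = 2L))
  sp <- pickPixels(gf$frame, cr, 2, ba, gf$geometry)
  v <- correctedIntensity(gf$frame)
  p <- clipProfile(cr)
  thr <- matrix(profileMean(p)[ba@pixelBin] + 2 * profileStd(p)[ba@pixelBin],
                96, 96)
  picked <- matrix(FALSE, 96, 96)
  picked[cbind(sp@pixelIndices %/% 96L + 1L, sp@pixelIndices %% 96L + 1L)] <- TRUE
  validPx <- !is.na(ba@pixelBin) & validBins(p)[ba@pixelBin]
  expect_true(all(v[picked & validPx] > thr[picked & validPx]))
  expect_true(all(v[!picked & validPx] <= thr[!picked & validPx]))
  # indices are strictly increasing, unique, in range
  expect_true(all(diff(sp@pixelIndices) > 0))
  expect_true(all(sp@pixelIndices >= 0 & sp@pixelIndices < 96^2))
  # an absurdly high threshold keeps nothing
  expect_identical(length(pickPixels(gf$frame, cr, 50, ba,
                                     gf$geometry)@pixelIndices), 0L)
  expect_error(pickPixels(gf$frame, cr, 0, ba, gf$geometry), "positive")
})

test_that("pixels of invalid bins are retained conservatively", {
  n <- 24L
  r <- buildRadiusMap(DetectorGeometry(n, n))
  ba <- buildBinAssignment(r, nBins = 4L)
  # empty bin 2 by masking it during clipping but not during picking
  holeMask <- matrix(ba@pixelBin == 2L, n, n); holeMask[is.na(holeMask)] <- FALSE
  pfClip <- preprocessFrame(matrix(10, n, n), mask = holeMask)
  cr <- sigmaClip(pfClip, ba, ClipConfig(snr = 3))
  pf <- preprocessFrame(matrix(10, n, n))
  sp <- pickPixels(pf, cr, 3, ba, DetectorGeometry(n, n))
  flat <- (which(holeMask, arr.ind = TRUE)[, 1] - 1L) * n +
    (which(holeMask, arr.ind = TRUE)[, 2] - 1L)
  expect_true(all(sort(flat) %in% sp@pixelIndices))
})

test_that("injected peak apexes survive a 3 sigma pick", {
  sc <- smallScene(n = 256L, nPeaks = 50L, seed = 71L, nBins = 48L)
  pf <- preprocessFrame(sc$sim$frames[[1]], mask = sc$sim$mask)
  cr <- sigmaClip(pf, sc$bins)
  sp <- pickPixels(pf, cr, 3, sc$bins, sc$g)
  apexFlat <- (round(sc$sim$peaks$row)) * 256L + round(sc$sim$peaks$col)
  expect_true(all(apexFlat %in% sp@pixelIndices))  # apex SNR >= 10 by design
})

test_that("the container round trip is bit-exact for ten synthetic frames", {
  sc <- smallScene(n = 96L, nPeaks = 5L, seed = 81L, nFrames = 10L,
                   nBins = 24L, maskFraction = 0.03)
  sf <- sparsifyFrames(sc$sim$frames, sc$g, mask = sc$sim$mask, nBins = 24L,
                       snrPick = 2)
  path <- withr::local_tempfile(fileext = ".h5")
  writeSparse(sf, path)
  back <- readSparse(path)
  expect_length(back, 10L)
  for (i in 1:10) {
    expect_identical(back[[i]]@pixelIndices, sf[[i]]@pixelIndices)
    expect_identical(back[[i]]@pixelValues, sf[[i]]@pixelValues)
    expect_identical(back[[i]]@backgroundMean, sf[[i]]@backgroundMean)
    expect_identical(back[[i]]@backgroundStd, sf[[i]]@backgroundStd)
    expect_identical(back[[i]]@frameId, i - 1L)
  }
  expect_identical(back[[1]]@binEdges, sf[[1]]@binEdges)
  expect_identical(back[[1]]@mask, sc$sim$mask)
  # CSR pointer invariants, checked on the raw datasets
  ptr <- as.integer(rhdf5::h5read(path, "entry/data/frame_ptr"))
  expect_length(ptr, 11L)
  expect_identical(ptr[1], 0L)
  expect_true(all(diff(ptr) >= 0L))
  expect_identical(ptr[11], sum(vapply(sf, function(x)
    length(x@pixelIndices), integer(1))))
})

test_that("an empty frame list yields a valid container", {
  path <- withr::local_tempfile(fileext = ".h5")
  writeSparse(list(), path)
  expect_identical(readSparse(path), list())
  expect_identical(as.integer(rhdf5::h5read(path, "entry/data/frame_ptr")), 0L)
})

test_that("a malformed container names the missing dataset", {
  path <- withr::local_tempfile(fileext = ".h5")
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "entry")
  rhdf5::h5createGroup(path, "entry/data")
  rhdf5::h5write(c(0L, 3L), path, "entry/data/frame_ptr")
  rhdf5::h5closeAll()
  expect_error(readSparse(path), "pixel_indices")
})

test_that("empirical keep fraction tracks the theory as the frame grows", {
  fracs <- vapply(c(128, 384), function(n) {
    gf <- gaussianFrame(n, sigma = 10, seed = 5)
    ba <- buildBinAssignment(gf$radius, nBins = max(8L, n %/% 16L))
    cr <- sigmaClip(gf$frame, ba, ClipConfig(snr = 5, errorModel = "azimuthal",
                                             maxIter = 2L))
    sp <- pickPixels(gf$frame, cr, 2, ba, gf$geometry)
    length(sp@pixelIndices) / n^2
  }, numeric(1))
  q <- theoreticalKeepFraction(2)
  expect_lt(abs(fracs[2] - q), abs(fracs[1] - q) + 3 * sqrt(q / 128^2))
  expect_lt(abs(fracs[2] - q), 3 * sqrt(q * (1 - q) / 384^2) + 0.002)
})
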