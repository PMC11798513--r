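# Shared fixture builders and independent oracles. Oracles are written from
# the definitions (two-pass sums, explicit histograms), never through the
# package's streaming/binned code paths they are meant to check.

# Two-pass weighted statistics straight from the definitions.
twoPassOracle <- function(v, w = rep(1, length(v))) {
  O <- sum(w)
  mu <- sum(w * v) / O
  VV <- sum(w * (v - mu)^2)
  O2 <- sum(w * w)
  list(omega = O, omega2 = O2, V = sum(w * v), VV = VV, mean = mu,
       std = sqrt(VV / O), sem = sqrt(VV * O2 / O^3))
}

relErr <- function(a, b) abs(a - b) / pmax(abs(b), .Machine$double.eps)

# The two-pixel ring of the bimodal worked example: values 1 and 199.
twoPixelBin <- function() {
  pf <- preprocessFrame(matrix(c(1, 199), 1, 2))
  ba <- buildBinAssignment(matrix(c(1, 1), 1, 2), nBins = 1L)
  list(pf = pf, ba = ba)
}

# Frame whose residuals about a known radial background are exactly
# N(0, sigma): background + sigma * Z, analysed with a fixed variance map.
gaussianFrame <- function(n, sigma = 10, base = 100, seed = 1) {
  g <- DetectorGeometry(as.integer(n), as.integer(n))
  r <- buildRadiusMap(g)
  mu <- base + 0.5 * base * exp(-r^2 / (2 * (0.3 * max(r))^2))
  set.seed(seed)
  raw <- matrix(mu + sigma * rnorm(length(mu)), n, n)
  pf <- preprocessFrame(raw, noiseModel = "variance-map",
                        varianceMap = matrix(sigma^2, n, n))
  list(geometry = g, radius = r, frame = pf, mu = mu, sigma = sigma)
}

# Small end-to-end simulated scene reused by several files.
smallScene <- function(n = 128L, nPeaks = 8L, seed = 11L, nFrames = 1L,
                       hit = TRUE, nBins = 32L, maskFraction = 0) {
  g <- DetectorGeometry(n, n)
  spec <- SimulationSpec(g, nPeaks = as.integer(nPeaks), seed = as.integer(seed),
                         maskFraction = maskFraction)
  sim <- simulateFrames(spec, nFrames = nFrames, hit = hit)
  ba <- buildBinAssignment(buildRadiusMap(g), mask = sim$mask, nBins = nBins)
  list(g = g, spec = spec, sim = sim, bins = ba)
}
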