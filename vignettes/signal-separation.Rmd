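---
title: "Separating isotropic background from Bragg peaks: methods and design"
author: "BraggSieve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating isotropic background from Bragg peaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BraggSieve)
```

## The model

A diffraction frame from a single crystal (or a serial-crystallography shot)
is modelled as the sum of two components: a smooth, isotropic scattering
background from amorphous material, which depends only on the distance $r$ of
a pixel from the beam center, and sparse, intense Bragg peaks. If the
background is isotropic, every pixel in a thin radial ring should see the same
photon flux after anisotropic corrections, so the ring population can be used
both to estimate the background level and, crucially, to estimate its
*uncertainty* without assuming any detector noise law.

Pixels are corrected before any statistic is formed:

$$ v_i \;=\; \frac{I_{\mathrm{raw},i} - I_{\mathrm{dark},i}}
{F_i \,\Omega_i \,P_i \,A_i \, I_0} $$

with flat field $F$, relative solid angle $\Omega$, polarization factor $P$,
apparent efficiency $A$ and incoming flux $I_0$. `preprocessFrame()` keeps the
numerator ("signal") and denominator ("norm") separate, because the weighted
ring statistics need both: pixel $i$ enters its ring with value
$v_i = \mathrm{signal}_i/\mathrm{norm}_i$ and weight
$\omega_i = c_i\,\mathrm{norm}_i$, where $c_i$ is the fraction of the pixel
assigned to the ring ($c_i = 1$ throughout, see below).

Per ring the package accumulates

$$ \Omega = \sum_i \omega_i,\quad \Omega_2 = \sum_i \omega_i^2,\quad
   V = \sum_i \omega_i v_i,\quad
   VV = \sum_i \omega_i\,(v_i - V/\Omega)^2 $$

so the weighted mean is $\mu_r = V/\Omega$. These four sums are the state of a
`WeightedAccumulator`: they can be built in one streaming pass
(`accumulate()`) and partial accumulators over disjoint pixel sets merge
exactly (`merge()`), with the cross term
$\frac{\Omega_A \Omega_B}{\Omega_{AB}}\left(\frac{V_A}{\Omega_A} -
\frac{V_B}{\Omega_B}\right)^2$ added to $VV$. This is what makes chunked and
parallel reduction possible; the test suite checks the single-pass/merged
results against plain two-pass sums to $10^{-10}$ relative over a thousand
random weighted sets and arbitrary merge orders. All accumulator arithmetic is
in double precision, which removes the catastrophic-cancellation concern that
motivates double-word tricks in single-precision GPU reductions.

## Three error models

Two different uncertainties must be distinguished: the uncertainty of the
*mean* (`sem`) and the uncertainty of a *pixel value* (`std`). For unit
weights they differ by $\sqrt{N}$; with weights the package uses the Kish
effective sample size $N_\mathrm{eff} = \Omega^2/\Omega_2$, so that
`sem = std / sqrt(N_eff)` and the unit-weight limit is exact. Everything
downstream (clipping, picking, peak SNR) is phrased in pixel-level `std`.

* **poisson** — counting statistics, $\lambda = \mu = \sigma^2$ per pixel;
  the per-pixel variance of the signal is propagated with squared
  coefficients: $\mathrm{sem}^2 = \sum_i c_i^2 \sigma_i^2 / \Omega^2$. Right
  for photon-counting detectors, wrong for anything with structure in the
  ring.
* **azimuthal** — the deviation measured inside the ring:
  $\mathrm{std}^2 = VV/\Omega$ (weighted population variance). Assumes
  nothing about the detector, at the price of more bin-to-bin variability.
* **hybrid** — azimuthal during clipping, Poisson on the trimmed ensemble
  for reporting, with the rate taken from the trimmed mean
  ($\sigma_i^2 = \max(\mu_r\,\mathrm{norm}_i, \text{floor})$).

Why the hybrid exists is best seen on a two-pixel ring with values
$\{1, 199\}$: the mean is 100, each pixel sits exactly $1\sigma$ from it under
the azimuthal model ($\sigma = 99$), but $10\sigma$ under the Poisson model
($\sigma = \sqrt{100} = 10$). Clipping such a bimodal ring with Poisson
uncertainties empties it entirely — a failure mode that silently destroys the
background estimate wherever strong peaks sit on a weak background. The
regression test for exactly this scenario is part of the suite.

```{r worked-example}
acc <- accumulate(WeightedAccumulator(), c(1, 199))
unlist(accumulatorStats(acc)[c("mean", "std")])
```

## Sigma clipping

`sigmaClip()` iterates per ring: estimate $(\mu_r, \sigma_r)$ under the
clipping model, discard pixels with $|v_i - \mu_r| > n\,\sigma_r$ (two-sided:
positive outliers are Bragg peaks, negative ones shadows), re-estimate, stop
when nothing is discarded or `maxIter` is reached. Numerical conventions, all
of which are deliberate choices where the procedure itself is
convention-free:

* Ties at exactly $n\sigma$ are **retained** (strict inequality rejects).
* Rings with fewer than 3 pixels are never clipped; a ring that loses all
  pixels is flagged invalid and triggers a warning, never an error.
* `maxIter` defaults to 5 with early exit; on well-behaved frames about 3
  iterations are typical and the tests assert a generous bound of 10.
* With `snr = "auto"` the cutoff is the Chauvenet-variant threshold
  $t(N) = \sqrt{2\ln\!\left(N/\sqrt{2\pi}\right)}$, the level at which a
  normal ring of the current size $N$ would be expected to lose a single
  member. It is recomputed each iteration as $N$ shrinks, evaluates to 2.7 at
  $N = 100$ and 3.5 at $N = 1000$, and is clamped at 0 below
  $N = \sqrt{2\pi}$ (a regime the minimum-population rule excludes anyway).

## Geometry and binning conventions

Pixel coordinates are 0-based with pixel centers at integer coordinates; the
beam center is fractional and may lie outside the frame. Radial bins are
equal-width over $[0, r_\max]$, half-open $[lo, hi)$ with the last bin
closed. No pixel splitting is performed ($c_i = 1$): splitting blurs the
azimuthal statistics and is exactly what this estimator avoids needing. The
radial coordinate is the plain detector radius (metres, or pixels when
`pixelSize = 1`); `radiusToQ()`/`qToResolution()` provide the linear
conversion when distance and wavelength are known. Bin-count defaults: 500
for 4M-class detectors, scaled down proportionally for the small synthetic
frames used in tests.

## Sparsification and densification

`pickPixels()` keeps an unmasked pixel iff $v_i > \mu_r + n\,\sigma_r$.
Assuming clipping has enforced a normal background, the expected keep
fraction is the normal upper tail $Q(n)$ — about 16%, 2.3% and 0.13% at
$n = 1, 2, 3$ — and with two numbers stored per retained pixel the maximum
compression ratio is $1/(2\,Q(n))$: 22x at $2\sigma$, and already above the
6.4x a kHz-rate 4M detector needs at $1.5\sigma$. Pixels whose ring
background is invalid are retained unconditionally: losing compression is
recoverable, losing signal is not.

The container (`writeSparse()`/`readSparse()`) is HDF5 following the NeXus
convention: retained indices/values of all frames concatenated CSR-style
under `/entry/data` (`frame_ptr`, `pixel_indices`, `pixel_values`), per-frame
background profiles under `/entry/background`, and the geometry provenance
(shape, beam center, pixel pitch, mask, radius-map hash) under
`/entry/geometry`. Indices are flat, row-major and 0-based. Values are stored
as 64-bit floats of the corrected intensity: the container's contract is a
bit-exact round trip of what was picked, and R's numeric type is double; a
32-bit value stream would halve the payload at the cost of that guarantee.
Any lossless HDF5 codec may wrap the datasets.

`densify()` rebuilds dense frames: retained pixels bit-exact, everything else
synthesized from the stored profile — noiseless ($\mu_r$), Gaussian
($\mu_r + \mathcal{N}(0, \sigma_r)$, the default, matching integrators that
model noise), or Poisson draws of $\mu_r$ (for software performing deep
counting-statistics analysis). Gaussian noise is left untruncated for float
output and truncated at zero only for integer output. Masked pixels and
pixels without a valid background get the sentinel $-1$ — shaded regions
cannot be reconstructed and must stay masked downstream. Reconstruction is
deterministic given (sparse frame, noise mode, seed).

## Peak finding and veto

`findPeaks()` registers a candidate pixel ($\mathrm{SNR} \ge$ `minSnr`
against its own ring's post-clip $\mu_r, \sigma_r$) as a peak when it is the
strict maximum of its `patchSize` x `patchSize` neighborhood (value ties
broken toward the smallest row-major index — the procedure needs *some*
deterministic rule and this one is order-independent) and at least
`minPixels` patch pixels pass the SNR condition; the apex counts toward
`minPixels`. Defaults (5x5 patch, SNR 3, 4 pixels) follow the published
comparison settings for this family of pickers; `sigmaFloor` exposes the
"noise level" floor used with Poissonian detectors. Per peak the
background-subtracted, intensity-weighted centroid (weights clamped at 0),
the summed background-subtracted intensity and its propagated deviation
$\sqrt{\sum \sigma_r^2}$ are recorded. Overlapping patches are reported
separately; merging is out of scope. Using the per-ring sigma rather than a
square-neighborhood variance matters most near the beam center, where ring
curvature puts steep radial structure inside any square window; the suite
demonstrates this with a sharp synthetic diffuse ring, counting false picks
for both estimators.

Peak lists export to the CXI HDF5 layout (`nPeaks`, `peakXPosRaw`,
`peakYPosRaw`, `peakTotalIntensity`, `peakSNR`, rows padded to a fixed
width), readable by standard serial-crystallography indexing pipelines; X is
the column and Y the row, 0-based. `vetoFrame()` implements the hit finder:
keep a frame iff it has at least `minPeaks` peaks.

## What the synthetic generator does and does not emulate

`simulateFrames()` draws Poisson counts of an analytic radial background (a
constant floor, a forward-scattering Gaussian centred at $r = 0$ and a
diffuse amorphous ring) plus 2D-Gaussian peaks whose apex amplitude is
`snr * sqrt(background)`, i.e. calibrated in local Poisson sigmas; a
horizontal strip of masked rows emulates a module gap. Defaults — 256x256
unit-test frames, 50 peaks of width 1 px with apex SNR uniform in [10, 50],
a 2% mask fraction, background floor of 50 counts — were chosen once as a
realistic low-background serial-crystallography regime at desk scale.
Poisson (not Gaussian) noise is used so the Poisson error model is exercised
honestly. Peaks are placed at least 15 px apart (3x the default patch) and
away from mask and borders, and the generator records exact centers,
amplitudes and SNRs as ground truth.

The generator deliberately omits: structure-factor physics, mosaicity and
partiality, detector point-spread, gain-stage artefacts of integrating
detectors, anisotropic or non-centrosymmetric backgrounds, and diffuse
scattering. Passing tests therefore demonstrate the statistical correctness
of the separation on isotropic-background data, not end-to-end
crystallographic quality on real beamline data.

## Problem sizes used by the checks

Unit tests run on 96-256 px frames. The statistical acceptance checks use a
seeded 2048x2048 pure-noise frame (4.2M pixels, 500 rings) for the empirical
2-sigma keep fraction, a 6-frame 256x256 stack for container round-trip and
noise-moment checks, and a 110-frame 512x512 stack (100 hit frames with 50
peaks each plus 10 matched pure-background frames, 128 rings) for
background/peak parameter recovery. These sizes give every statistical
assertion comfortable power while keeping the whole suite runnable on a
single CPU in minutes.

## Known limitations

* Anisotropic backgrounds (e.g. stretched-film scattering in fixed-target
  mode) violate the core isotropy assumption and are not addressable here;
  shadows must be masked, not modelled.
* Single-module, untilted geometry only: no PONI-style tilts, no
  multi-module layouts; the radius map is a plain Euclidean distance.
* The hybrid model's reported sigma assumes the trimmed ring is
  Poisson-like; for steep radial gradients inside a bin the azimuthal model
  is the safer reporting choice (this is why the curvature regression test
  clips with `errorModel = "azimuthal"`).
* `readCxi()` recovers only what the CXI layout stores; the patch-level
  `sigma` and `nPixels` fields are not part of that format.
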