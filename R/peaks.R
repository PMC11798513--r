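#' SNR-based Bragg peak finder
#'
#' Peak picking on top of the clipped background, in the spirit of
#' peakfinder8: a pixel is a candidate when its corrected intensity exceeds
#' its ring's background mean by at least `minSnr` ring sigmas; a candidate is
#' an apex when it is the strict maximum of its local patch (ties broken in
#' favor of the smallest row-major index); an apex is registered as a peak
#' when at least `minPixels` patch pixels (apex included) meet the SNR
#' condition. Because the background sigma is measured along the ring, the
#' strong curvature of Debye-Scherrer rings near the beam center does not
#' inflate it the way a square-neighborhood variance would.
#'
#' For each peak the background-subtracted intensity-weighted centroid
#' (weights clamped at 0), the summed background-subtracted intensity over the
#' qualifying patch pixels, and the propagated deviation of that sum
#' (`sqrt(sum sigma_r^2)`) are recorded. Pixels that are masked, or whose bin
#' has no valid background, are skipped; patches are clipped at the frame
#' border.
#'
#' @param frame a [PreprocessedFrame-class].
#' @param clip a [ClipResult-class] on the same geometry.
#' @param bins the [BinAssignment-class] used for `clip`.
#' @param config a [PeakFinderConfig()].
#' @param frameId integer identifier recorded in the result.
#' @return A [PeakList-class]; centroids are 0-based fractional pixels.
#' @export
findPeaks <- function(frame, clip, bins, config = PeakFinderConfig(),
                      frameId = 0L) {
  stopifnot(is(frame, "PreprocessedFrame"), is(clip, "ClipResult"),
            is(bins, "BinAssignment"), is(config, "PeakFinderConfig"))
  validObject(config)
  prof <- clip@profile
  v <- frame@signal / frame@norm
  b <- bins@pixelBin
  nr <- nrow(v); nc <- ncol(v)
  mu <- matrix(prof@mean[b], nr, nc)
  sdr <- matrix(pmax(prof@std[b], config@sigmaFloor), nr, nc)
  ok <- !frame@mask & !is.na(b) & is.finite(mu) & is.finite(sdr) & sdr > 0
  snr <- matrix(NA_real_, nr, nc)
  snr[ok] <- (v[ok] - mu[ok]) / sdr[ok]
  cand <- which(ok & !is.na(snr) & snr >= config@minSnr, arr.ind = TRUE)
  half <- (config@patchSize - 1L) %/% 2L
  peaks <- vector("list", nrow(cand))
  np <- 0L
  if (nrow(cand)) {
    ## visit candidates in row-major order so the tie-break is by index
    ord <- order(cand[, 1L], cand[, 2L])
    for (k in ord) {
      r0 <- cand[k, 1L]; c0 <- cand[k, 2L]
      rows <- max(1L, r0 - half):min(nr, r0 + half)
      cols <- max(1L, c0 - half):min(nc, c0 + half)
      pv <- v[rows, cols, drop = FALSE]
      pok <- ok[rows, cols, drop = FALSE]
      v0 <- v[r0, c0]
      ## strict maximum among usable patch pixels; equal values lose to the
      ## smaller row-major index
      if (any(pok & pv > v0)) next
      if (any(pok & pv == v0)) {
        flat <- outer((rows - 1L) * nc, cols - 1L, `+`)
        if (min(flat[pok & pv == v0]) < (r0 - 1L) * nc + (c0 - 1L)) next
      }
      psnr <- snr[rows, cols, drop = FALSE]
      qual <- pok & !is.na(psnr) & psnr >= config@minSnr
      if (sum(qual) < config@minPixels) next
      resid <- pv - mu[rows, cols, drop = FALSE]
      wpos <- pmax(resid, 0) * qual
      rr <- matrix(rows - 1L, length(rows), length(cols))
      cc <- matrix(cols - 1L, length(rows), length(cols), byrow = TRUE)
      wsum <- sum(wpos)
      cen <- if (wsum > 0) c(sum(wpos * rr), sum(wpos * cc)) / wsum
             else c(r0 - 1L, c0 - 1L)
      np <- np + 1L
      peaks[[np]] <- data.frame(
        row = cen[1L], col = cen[2L],
        intensity = sum(resid[qual]),
        sigma = sqrt(sum(sdr[rows, cols, drop = FALSE][qual]^2)),
        snr = snr[r0, c0], nPixels = sum(qual))
    }
  }
  tab <- if (np) do.call(rbind, peaks[seq_len(np)])
         else data.frame(row = numeric(0), col = numeric(0),
                         intensity = numeric(0), sigma = numeric(0),
                         snr = numeric(0), nPixels = integer(0))
  new("PeakList", frameId = as.integer(frameId), peaks = tab)
}

#' Peak-count veto
#'
#' Keep/discard decision for one frame based on its Bragg-peak count, the
#' hit-finding step of a serial-crystallography pipeline: a frame is kept iff
#' it has at least `minPeaks` peaks. The threshold is meant to be adjustable
#' live; 0 keeps everything.
#'
#' @param peaklist a [PeakList-class].
#' @param minPeaks non-negative count threshold.
#' @return TRUE to keep the frame, FALSE to discard it.
#' @export
vetoFrame <- function(peaklist, minPeaks) {
  stopifnot(is(peaklist, "PeakList"), minPeaks >= 0)
  nPeaks(peaklist) >= minPeaks
}

#' Write / read peak lists in CXI format
#'
#' Stores per-frame peak lists in the HDF5 layout consumed by CrystFEL:
#' datasets `nPeaks`, `peakXPosRaw`, `peakYPosRaw`, `peakTotalIntensity` and
#' `peakSNR` under `/entry_1/result_1`, with one fixed-width row per frame
#' padded to `maxPeaks` (the valid count is `nPeaks`). X is the column and Y
#' the row coordinate, 0-based.
#'
#' @param peaklists list of [PeakList-class] objects, one per frame.
#' @param path output `.cxi`/`.h5` path (overwritten).
#' @param maxPeaks row width of the padded datasets.
#' @return `writeCxi()` returns `path` invisibly; `readCxi()` a list of
#'   [PeakList-class] objects (the fields stored in CXI; patch-level fields
#'   `sigma` and `nPixels` are not part of the format and read back as NA).
#' @export
writeCxi <- function(peaklists, path, maxPeaks = 1024L) {
  stopifnot(is.list(peaklists),
            all(vapply(peaklists, is, logical(1), "PeakList")))
  nF <- length(peaklists)
  counts <- vapply(peaklists, nPeaks, integer(1))
  if (any(counts > maxPeaks))
    stop("a frame has more than 'maxPeaks' peaks; raise maxPeaks")
  pad <- function(field) {
    m <- matrix(0, maxPeaks, nF)    # on-disk shape (nF, maxPeaks), C order
    for (i in seq_len(nF)) {
      n <- counts[i]
      if (n) m[seq_len(n), i] <- peaklists[[i]]@peaks[[field]]
    }
    m
  }
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll())
  rhdf5::h5createGroup(path, "entry_1")
  rhdf5::h5createGroup(path, "entry_1/result_1")
  rhdf5::h5write(as.integer(counts), path, "entry_1/result_1/nPeaks")
  rhdf5::h5write(pad("col"), path, "entry_1/result_1/peakXPosRaw")
  rhdf5::h5write(pad("row"), path, "entry_1/result_1/peakYPosRaw")
  rhdf5::h5write(pad("intensity"), path, "entry_1/result_1/peakTotalIntensity")
  rhdf5::h5write(pad("snr"), path, "entry_1/result_1/peakSNR")
  invisible(path)
}

#' @rdname writeCxi
#' @export
readCxi <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  on.exit(rhdf5::h5closeAll())
  ls <- rhdf5::h5ls(path)
  contents <- sub("^/", "", file.path(ls$group, ls$name))
  counts <- as.integer(.h5ReadOrStop(path, "entry_1/result_1/nPeaks",
                                     contents))
  x <- .h5ReadOrStop(path, "entry_1/result_1/peakXPosRaw", contents)
  y <- .h5ReadOrStop(path, "entry_1/result_1/peakYPosRaw", contents)
  it <- .h5ReadOrStop(path, "entry_1/result_1/peakTotalIntensity", contents)
  sn <- .h5ReadOrStop(path, "entry_1/result_1/peakSNR", contents)
  lapply(seq_along(counts), function(i) {
    n <- counts[i]
    sel <- seq_len(n)
    new("PeakList", frameId = i - 1L, peaks = data.frame(
      row = as.numeric(y[sel, i]), col = as.numeric(x[sel, i]),
      intensity = as.numeric(it[sel, i]), sigma = rep(NA_real_, n),
      snr = as.numeric(sn[sel, i]), nPixels = rep(NA_integer_, n)))
  })
}
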