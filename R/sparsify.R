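#' Analytic keep fraction of the sparsification threshold
#'
#' Expected fraction of pure-background pixels retained when keeping pixels
#' above the background mean plus `n` standard deviations, assuming sigma
#' clipping has enforced a normal background distribution: the standard-normal
#' upper-tail probability Q(n). About 16% of pixels survive n = 1, 2.3%
#' n = 2 and 0.13% n = 3.
#'
#' @param n picking threshold in sigma units (any real).
#' @return Upper-tail probability in `[0, 1]`.
#' @examples
#' theoreticalKeepFraction(2)     # ~0.0228
#' @export
theoreticalKeepFraction <- function(n) pnorm(n, lower.tail = FALSE)

#' Maximum theoretical compression ratio
#'
#' Each retained pixel stores two numbers (position and value), so a keep
#' fraction Q(n) compresses at most by `1 / (2 * Q(n))`, neglecting the
#' storage of the background profile and any lossless codec on top. A 2-sigma
#' cutoff gives 22x; 1.5 sigma about 7.5x.
#'
#' @param n picking threshold in sigma units, > 0.
#' @return Compression ratio (fold), monotonically increasing in `n`.
#' @export
theoreticalCompressionRatio <- function(n) {
  stopifnot(all(n > 0))
  1 / (2 * theoreticalKeepFraction(n))
}

#' Retain pixels above the clipped background
#'
#' Lossy sparsification of one frame: an unmasked pixel is retained iff its
#' corrected intensity strictly exceeds its ring's background mean plus
#' `n` times the ring's standard deviation. Pixels falling in bins whose
#' background is invalid (emptied during clipping, or out of range) are always
#' retained — losing signal is worse than losing compression. Retained values
#' are bit-exact copies of the corrected intensity.
#'
#' @param frame a [PreprocessedFrame-class].
#' @param clip a [ClipResult-class] computed on the same geometry.
#' @param n picking threshold SNR_pick, > 0.
#' @param bins the [BinAssignment-class] used for `clip`.
#' @param geometry the [DetectorGeometry-class] (stored for provenance).
#' @param frameId integer identifier stored in the container.
#' @return A [SparseFrame-class].
#' @export
pickPixels <- function(frame, clip, n, bins, geometry, frameId = 0L) {
  stopifnot(is(frame, "PreprocessedFrame"), is(clip, "ClipResult"),
            is(bins, "BinAssignment"), is(geometry, "DetectorGeometry"))
  if (n <= 0) stop("'n' (SNR_pick) must be positive")
  prof <- clip@profile
  if (length(prof@mean) != bins@nBins)
    stop("clip profile does not match the bin assignment")
  v <- frame@signal / frame@norm
  b <- bins@pixelBin
  mu <- prof@mean[b]
  sd <- prof@std[b]
  binOk <- !is.na(b) & prof@valid[ifelse(is.na(b), 1L, b)]
  retain <- !frame@mask & (!binOk | (v > mu + n * sd))
  retain[is.na(retain)] <- TRUE   # unmasked pixel, unknown background
  retain <- retain & !frame@mask
  nr <- nrow(v); nc <- ncol(v)
  which2 <- which(retain, arr.ind = TRUE)
  flat <- (which2[, 1L] - 1L) * nc + (which2[, 2L] - 1L)  # row-major, 0-based
  o <- order(flat)
  new("SparseFrame",
      pixelIndices = as.integer(flat[o]), pixelValues = v[retain][o],
      backgroundMean = ifelse(prof@valid, prof@mean, NaN),
      backgroundStd = ifelse(prof@valid, prof@std, NaN),
      binEdges = bins@binEdges, dim = c(nr, nc),
      beamCenter = geometry@beamCenter, pixelSize = geometry@pixelSize,
      mask = frame@mask, frameId = as.integer(frameId),
      threshold = as.numeric(n))
}

## ---- HDF5/NeXus container -------------------------------------------------
## Layout (CSR-style ragged concatenation across frames):
##   /entry                    @NX_class = NXentry
##     /data                   @NX_class = NXdata
##        frame_ptr[nF+1]  pixel_indices[nnz]  pixel_values[nnz]
##        frame_id[nF]     threshold[nF]
##     /background             @NX_class = NXcollection
##        bin_edges[nB+1]  mean[nF, nB]  std[nF, nB]
##     /geometry                @NX_class = NXcollection
##        radius_map_hash  beam_center[2]  pixel_size  shape[2]  mask[nr, nc]

.h5SetNX <- function(fid, name, class) {
  gid <- rhdf5::H5Gopen(fid, name)
  on.exit(rhdf5::H5Gclose(gid))
  rhdf5::h5writeAttribute(class, gid, "NX_class")
}

#' Write / read the sparse-frame container
#'
#' Stores a sequence of [SparseFrame-class] objects sharing one geometry in an
#' HDF5 container following the NeXus convention, with the retained pixels of
#' all frames concatenated CSR-style (`frame_ptr` holds the cumulative
#' offsets, length `nFrames + 1`, starting at 0). The round trip is lossless:
#' `readSparse(writeSparse(x))` restores indices and values bit-exact.
#'
#' @param frames list of [SparseFrame-class] objects with consistent geometry.
#' @param path output `.h5` path (overwritten).
#' @return `writeSparse()` returns `path` invisibly; `readSparse()` a list of
#'   [SparseFrame-class] objects.
#' @export
writeSparse <- function(frames, path) {
  stopifnot(is.list(frames),
            all(vapply(frames, is, logical(1), "SparseFrame")))
  if (length(frames) > 1L) {
    ref <- frames[[1L]]
    same <- vapply(frames, function(f)
      identical(f@dim, ref@dim) && identical(f@binEdges, ref@binEdges) &&
        identical(f@beamCenter, ref@beamCenter) &&
        identical(f@pixelSize, ref@pixelSize), logical(1))
    if (!all(same)) stop("frames do not share a consistent geometry")
  }
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createGroup(path, "entry")
  rhdf5::h5createGroup(path, "entry/data")
  rhdf5::h5createGroup(path, "entry/background")
  rhdf5::h5createGroup(path, "entry/geometry")
  nF <- length(frames)
  counts <- vapply(frames, function(f) length(f@pixelIndices), integer(1))
  ptr <- c(0L, cumsum(counts))
  idx <- unlist(lapply(frames, slot, "pixelIndices"))
  val <- unlist(lapply(frames, slot, "pixelValues"))
  rhdf5::h5write(as.integer(ptr), path, "entry/data/frame_ptr")
  rhdf5::h5write(if (length(idx)) as.integer(idx) else integer(0),
                 path, "entry/data/pixel_indices")
  rhdf5::h5write(if (length(val)) as.numeric(val) else numeric(0),
                 path, "entry/data/pixel_values")
  rhdf5::h5write(vapply(frames, slot, integer(1), "frameId"),
                 path, "entry/data/frame_id")
  rhdf5::h5write(vapply(frames, slot, numeric(1), "threshold"),
                 path, "entry/data/threshold")
  if (nF) {
    nB <- length(frames[[1L]]@backgroundMean)
    rhdf5::h5write(frames[[1L]]@binEdges, path, "entry/background/bin_edges")
    rhdf5::h5write(matrix(unlist(lapply(frames, slot, "backgroundMean")), nB, nF),
                   path, "entry/background/mean")
    rhdf5::h5write(matrix(unlist(lapply(frames, slot, "backgroundStd")), nB, nF),
                   path, "entry/background/std")
    rhdf5::h5write(geometryHash(frames[[1L]]@dim, frames[[1L]]@beamCenter,
                                frames[[1L]]@pixelSize),
                   path, "entry/geometry/radius_map_hash")
    rhdf5::h5write(frames[[1L]]@beamCenter, path, "entry/geometry/beam_center")
    rhdf5::h5write(frames[[1L]]@pixelSize, path, "entry/geometry/pixel_size")
    rhdf5::h5write(frames[[1L]]@dim, path, "entry/geometry/shape")
    storage.mode(frames[[1L]]@mask) <- "integer"
    rhdf5::h5write(frames[[1L]]@mask, path, "entry/geometry/mask")
  } else {
    rhdf5::h5write(numeric(0), path, "entry/background/bin_edges")
  }
  fid <- rhdf5::H5Fopen(path)
  .h5SetNX(fid, "entry", "NXentry")
  .h5SetNX(fid, "entry/data", "NXdata")
  .h5SetNX(fid, "entry/background", "NXcollection")
  .h5SetNX(fid, "entry/geometry", "NXcollection")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

.h5ReadOrStop <- function(path, name, contents) {
  if (!name %in% contents)
    stop("malformed sparse container: missing dataset '", name, "'")
  rhdf5::h5read(path, name)
}

#' @rdname writeSparse
#' @export
readSparse <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  on.exit(rhdf5::h5closeAll())
  ls <- rhdf5::h5ls(path)
  contents <- sub("^/", "", file.path(ls$group, ls$name))
  ptr <- as.integer(.h5ReadOrStop(path, "entry/data/frame_ptr", contents))
  nF <- length(ptr) - 1L
  if (nF == 0L) return(list())
  idx <- as.integer(.h5ReadOrStop(path, "entry/data/pixel_indices", contents))
  val <- as.numeric(.h5ReadOrStop(path, "entry/data/pixel_values", contents))
  fid <- as.integer(.h5ReadOrStop(path, "entry/data/frame_id", contents))
  thr <- as.numeric(.h5ReadOrStop(path, "entry/data/threshold", contents))
  edges <- as.numeric(.h5ReadOrStop(path, "entry/background/bin_edges",
                                    contents))
  mu <- .h5ReadOrStop(path, "entry/background/mean", contents)
  sd <- .h5ReadOrStop(path, "entry/background/std", contents)
  bc <- as.numeric(.h5ReadOrStop(path, "entry/geometry/beam_center", contents))
  ps <- as.numeric(.h5ReadOrStop(path, "entry/geometry/pixel_size", contents))
  shape <- as.integer(.h5ReadOrStop(path, "entry/geometry/shape", contents))
  msk <- .h5ReadOrStop(path, "entry/geometry/mask", contents)
  msk <- matrix(as.logical(msk), shape[1L], shape[2L])
  mu <- matrix(mu, ncol = nF); sd <- matrix(sd, ncol = nF)
  lapply(seq_len(nF), function(i) {
    sel <- if (ptr[i + 1L] > ptr[i]) (ptr[i] + 1L):ptr[i + 1L] else integer(0)
    new("SparseFrame", pixelIndices = idx[sel], pixelValues = val[sel],
        backgroundMean = mu[, i], backgroundStd = sd[, i], binEdges = edges,
        dim = shape, beamCenter = bc, pixelSize = ps, mask = msk,
        frameId = fid[i], threshold = thr[i])
  })
}
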