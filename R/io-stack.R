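#' Dense frame-stack HDF5 I/O
#'
#' Minimal reader/writer for stacks of dense frames in an HDF5 file, used as
#' the input side of the sparsification pipeline and the output side of
#' densification. Frames are stored in one 3D dataset with the frame index as
#' the last R dimension.
#'
#' @param frames list of numeric matrices of equal shape.
#' @param path `.h5` file path.
#' @param dataset dataset name inside the file.
#' @return `writeFrameStack()` returns `path` invisibly; `readFrameStack()` a
#'   list of matrices.
#' @export
writeFrameStack <- function(frames, path, dataset = "entry/data/data") {
  stopifnot(is.list(frames), length(frames) >= 1L)
  d <- dim(frames[[1L]])
  arr <- array(unlist(frames), dim = c(d, length(frames)))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll())
  parts <- strsplit(dataset, "/", fixed = TRUE)[[1L]]
  for (i in seq_len(length(parts) - 1L))
    rhdf5::h5createGroup(path, paste(parts[seq_len(i)], collapse = "/"))
  rhdf5::h5write(arr, path, dataset)
  invisible(path)
}

#' @rdname writeFrameStack
#' @export
readFrameStack <- function(path, dataset = "entry/data/data") {
  if (!file.exists(path)) stop("no such file: ", path)
  on.exit(rhdf5::h5closeAll())
  arr <- rhdf5::h5read(path, dataset)
  if (length(dim(arr)) == 2L) return(list(arr))
  lapply(seq_len(dim(arr)[3L]), function(i) arr[, , i])
}

#' Sparsify a stack of raw frames
#'
#' Convenience pipeline over [preprocessFrame()], [sigmaClip()] and
#' [pickPixels()]: corrects each raw frame, estimates its radial background
#' with iterative sigma clipping and keeps only pixels above
#' `mean + snrPick * sigma`. The geometry (and hence the bin assignment) is
#' fixed across the stack and computed once.
#'
#' @param frames list of raw frame matrices.
#' @param geometry a [DetectorGeometry-class].
#' @param mask optional logical matrix.
#' @param nBins number of radial bins.
#' @param snrPick picking threshold in sigma units.
#' @param clipConfig a [ClipConfig()].
#' @param corrections a [CorrectionSet()].
#' @return List of [SparseFrame-class], frame ids 0-based in stack order.
#' @export
sparsifyFrames <- function(frames, geometry, mask = NULL, nBins = 500L,
                           snrPick = 2, clipConfig = ClipConfig(),
                           corrections = CorrectionSet()) {
  stopifnot(is.list(frames))
  bins <- buildBinAssignment(buildRadiusMap(geometry), mask, nBins)
  lapply(seq_along(frames), function(i) {
    pf <- preprocessFrame(frames[[i]], corrections, mask)
    cr <- sigmaClip(pf, bins, clipConfig)
    pickPixels(pf, cr, snrPick, bins, geometry, frameId = i - 1L)
  })
}
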