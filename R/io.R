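## Sample container: a single self-contained file holding the flow array,
## the per-frame validity mask and the trial metadata. Layout:
##   bytes 0-3   magic "HCDS"
##   bytes 4-7   int32 header length L (little endian)
##   L bytes     JSON header: dims, validMask, spec fields, md5 of payload
##   rest        float64 payload, little endian, column-major flow array
## The float64 payload makes write -> read an exact round trip.

.specAsList <- function(sp) {
  list(preswitch = sp@preswitch, switchAngle = sp@switchAngle,
       postswitch = sp@postswitch, nFrames = sp@nFrames,
       switchFrame = sp@switchFrame,
       blackoutFrames = as.integer(sp@blackoutFrames),
       conditionLabel = sp@conditionLabel,
       repetition = sp@repetition, seed = sp@seed)
}

.specFromList <- function(l) {
  TrialSpec(preswitch = l$preswitch, switchAngle = l$switchAngle,
            nFrames = l$nFrames, switchFrame = l$switchFrame,
            blackoutFrames = unlist(l$blackoutFrames),
            conditionLabel = l$conditionLabel,
            repetition = l$repetition, seed = l$seed)
}

.payloadMd5 <- function(raw) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(raw, tmp)
  unname(tools::md5sum(tmp))
}

#' Write a flow sample to a container file
#'
#' Lossless single-file storage of the flow array, validity mask and trial
#' metadata, with an embedded checksum for corruption detection. The same
#' sample always produces a byte-identical file.
#'
#' @param sample a [FlowSample-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readFlowSample()], [exportFlo()]
#' @export
writeFlowSample <- function(sample, path) {
  stopifnot(is(sample, "FlowSample"))
  payload <- writeBin(as.numeric(sample@flow), raw(), size = 8L,
                      endian = "little")
  header <- jsonlite::toJSON(list(
    dims = dim(sample@flow),
    validMask = sample@validMask,
    spec = .specAsList(sample@spec),
    md5 = .payloadMd5(payload)), auto_unbox = TRUE, digits = NA)
  hraw <- charToRaw(as.character(header))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("HCDS"), con)
  writeBin(length(hraw), con, size = 4L, endian = "little")
  writeBin(hraw, con)
  writeBin(payload, con)
  invisible(path)
}

#' Read a flow sample container
#'
#' Restores the exact [FlowSample-class] written by [writeFlowSample()].
#' Truncated files and checksum mismatches raise a corruption error.
#'
#' @param path file path.
#' @return A [FlowSample-class].
#' @export
readFlowSample <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, raw(), 4L)
  if (!identical(rawToChar(magic), "HCDS"))
    stop("corrupt sample file: bad magic")
  hlen <- readBin(con, integer(), 1L, size = 4L, endian = "little")
  if (length(hlen) != 1L || hlen <= 0L)
    stop("corrupt sample file: bad header length")
  hraw <- readBin(con, raw(), hlen)
  if (length(hraw) != hlen) stop("corrupt sample file: truncated header")
  hdr <- jsonlite::fromJSON(rawToChar(hraw))
  dims <- as.integer(hdr$dims)
  nvals <- prod(dims)
  payload <- readBin(con, raw(), nvals * 8L)
  if (length(payload) != nvals * 8L)
    stop("corrupt sample file: truncated payload")
  if (!identical(unname(.payloadMd5(payload)), unname(hdr$md5)))
    stop("corrupt sample file: checksum mismatch")
  vals <- readBin(payload, numeric(), nvals, size = 8L, endian = "little")
  new("FlowSample", flow = array(vals, dims),
      validMask = as.logical(hdr$validMask),
      spec = .specFromList(hdr$spec))
}

#' Export one frame in the Middlebury .flo format
#'
#' Writes the standard dense-optical-flow file: float32 magic 202021.25,
#' little-endian int32 width and height, then row-major interleaved
#' (u, v) float32 pairs. Useful for viewing frames in external flow
#' visualizers; the vertical component is written in this package's
#' elevation-positive-up convention. A blacked-out frame is exported as
#' zeros with a warning.
#'
#' @param sample a [FlowSample-class].
#' @param frame 1-based frame index.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
exportFlo <- function(sample, frame, path) {
  stopifnot(is(sample, "FlowSample"))
  nf <- nFrames(sample)
  if (frame < 1L || frame > nf) stop("frame out of range")
  if (!sample@validMask[frame])
    warning("frame ", frame, " is a blackout frame; exporting zeros")
  fr <- sample@flow[, , , frame]
  h <- dim(fr)[1]; w <- dim(fr)[2]
  inter <- aperm(fr, c(3L, 2L, 1L))   # (component, x, y), y = row
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(202021.25, con, size = 4L, endian = "little")
  writeBin(c(as.integer(w), as.integer(h)), con, size = 4L,
           endian = "little")
  writeBin(as.numeric(inter), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a Middlebury .flo file
#'
#' @param path file path.
#' @return An `H x W x 2` numeric array (float32 precision).
#' @export
readFlo <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, numeric(), 1L, size = 4L, endian = "little")
  if (abs(magic - 202021.25) > 1e-2) stop("not a .flo file")
  wh <- readBin(con, integer(), 2L, size = 4L, endian = "little")
  w <- wh[1]; h <- wh[2]
  vals <- readBin(con, numeric(), 2L * w * h, size = 4L, endian = "little")
  inter <- array(vals, c(2L, w, h))
  aperm(inter, c(3L, 2L, 1L))
}
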