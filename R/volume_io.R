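## MRC2014 input/output and slice-level preprocessing.
##
## The MRC format is a 1024-byte header (56 4-byte words + 800 bytes of
## labels) followed by the voxel grid with x fastest and z slowest.  Volumes
## are held in memory as (z, y, x) arrays so that slice extraction along z is
## the natural first-index subset.  Writes always use mode 2 (float32),
## which is lossless for everything this package generates; reads accept
## modes 0 (int8), 1 (int16), 2 (float32) and 6 (uint16).

.mrcModeInfo <- function(mode) {
  switch(as.character(mode),
    "0" = list(what = "integer", size = 1L, signed = TRUE),
    "1" = list(what = "integer", size = 2L, signed = TRUE),
    "2" = list(what = "numeric", size = 4L, signed = TRUE),
    "6" = list(what = "integer", size = 2L, signed = FALSE),
    stop(sprintf("unsupported MRC mode %s", mode)))
}

.readMRCRaw <- function(path) {
  if (!file.exists(path)) stop(sprintf("MRC file not found: '%s'", path))
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 1024L)
  if (length(hdr) < 1024L)
    stop(sprintf("unreadable MRC header in '%s' (file too short)", path))
  word <- function(i, what = "integer")  # 1-based 4-byte header word
    readBin(hdr[(4L * (i - 1L) + 1L):(4L * i)], what, size = 4L,
            endian = "little")
  nx <- word(1); ny <- word(2); nz <- word(3); mode <- word(4)
  mx <- word(8)
  cellx <- word(11, "numeric")
  nsymbt <- word(24)
  if (any(c(nx, ny, nz) < 1L))
    stop(sprintf("'%s' does not contain 3-D data (dims %d x %d x %d)",
                 path, nx, ny, nz))
  if (nsymbt > 0) invisible(readBin(con, "raw", n = nsymbt))
  info <- .mrcModeInfo(mode)
  n <- as.double(nx) * ny * nz
  dat <- readBin(con, info$what, n = n, size = info$size,
                 signed = info$signed, endian = "little")
  if (length(dat) < n)
    stop(sprintf("truncated MRC file '%s': expected %g voxels, found %d",
                 path, n, length(dat)))
  apx <- if (mx > 0 && cellx > 0) cellx / mx else 1
  list(data = array(as.double(dat), dim = c(nx, ny, nz)), apix = apx)
}

.writeMRCRaw <- function(a, apix, path) {
  ## a: array dim (nx, ny, nz), x fastest in memory (R column-major)
  d <- dim(a)
  con <- file(path, "wb")
  on.exit(close(con))
  wInt <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wFlt <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wInt(c(d, 2L))                       # nx ny nz mode
  wInt(c(0L, 0L, 0L))                  # nxstart..
  wInt(d)                              # mx my mz
  wFlt(d * apix)                       # cella
  wFlt(c(90, 90, 90))                  # cellb
  wInt(c(1L, 2L, 3L))                  # mapc mapr maps
  wFlt(c(min(a), max(a), mean(a)))     # dmin dmax dmean
  wInt(c(0L, 0L))                      # ispg nsymbt
  wInt(rep(0L, 25L))                   # extra
  wFlt(c(0, 0, 0))                     # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wFlt(stats::sd(a))                   # rms
  wInt(0L)                             # nlabl
  writeBin(raw(800L), con)             # labels
  writeBin(as.double(a), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a tomogram volume from an MRC file
#'
#' @param path path to a 3-D MRC file (modes 0, 1, 2 or 6).
#' @return A [TomoVolume-class] with voxels indexed (z, y, x) — z slowest,
#'   as stored on disk — and `apix` taken from the header cell dimensions.
#' @export
#' @examples
#' v <- new("TomoVolume", voxels = array(rnorm(4 * 8 * 8), c(4, 8, 8)),
#'          apix = 13.26)
#' p <- tempfile(fileext = ".mrc")
#' writeVolume(v, p)
#' readVolume(p)
readVolume <- function(path) {
  raw <- .readMRCRaw(path)
  new("TomoVolume", voxels = aperm(raw$data, c(3, 2, 1)), apix = raw$apix)
}

#' Write a tomogram volume to an MRC file
#'
#' Data are written as 32-bit floats (mode 2) regardless of input type, so
#' round trips are lossless to float precision.
#'
#' @param volume a [TomoVolume-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "TomoVolume"))
  .writeMRCRaw(aperm(volume@voxels, c(3, 2, 1)), volume@apix, path)
}

#' Read/write one tilt's movie frames as a multi-frame MRC stack
#'
#' Frames occupy the z axis of the MRC file. Dose and tilt metadata, which
#' MRC cannot carry, live in a JSON sidecar (`<path>.json`).
#'
#' @param stack a [FrameStack-class].
#' @param path MRC path (sidecar written/read at `<path>.json`).
#' @return `writeFrameStack`: `path` invisibly; `readFrameStack`: a
#'   [FrameStack-class].
#' @export
writeFrameStack <- function(stack, path) {
  stopifnot(is(stack, "FrameStack"))
  ## frames array (rows, cols, frame): rows map to y, cols to x
  .writeMRCRaw(aperm(stack@frames, c(2, 1, 3)), stack@apix, path)
  jsonlite::write_json(
    list(dose_per_frame = stack@dosePerFrame, tilt_angle = stack@tiltAngle,
         apix = stack@apix),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeFrameStack
#' @export
readFrameStack <- function(path) {
  raw <- .readMRCRaw(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new("FrameStack", frames = aperm(raw$data, c(2, 1, 3)),
      dosePerFrame = meta$dose_per_frame, tiltAngle = meta$tilt_angle,
      apix = meta$apix)
}

#' Centered crop of a slice
#'
#' Crops a `size` x `size` window centered on the slice (offset
#' `floor((dim - size) / 2)` on each axis), e.g. 1024 px acquisition slices
#' to the 960 px network input.
#'
#' @param slice a [SliceImage-class].
#' @param size target edge length in pixels; both slice dimensions must be
#'   at least `size`.
#' @return The cropped [SliceImage-class]; `apix` is unchanged.
#' @export
cropCenter <- function(slice, size) {
  stopifnot(is(slice, "SliceImage"))
  d <- dim(slice@pixels)
  for (ax in 1:2) if (d[ax] < size)
    stop(sprintf("slice dimension %d (%d px) is smaller than crop size %d",
                 ax, d[ax], size))
  off <- (d - size) %/% 2L
  new("SliceImage",
      pixels = slice@pixels[off[1] + seq_len(size), off[2] + seq_len(size),
                            drop = FALSE],
      apix = slice@apix, sourceZ = slice@sourceZ)
}

#' Standardize a slice to zero mean and unit variance
#'
#' Constant slices cannot be standardized and are returned as all zeros with
#' a warning.
#'
#' @param slice a [SliceImage-class].
#' @return The standardized [SliceImage-class].
#' @export
normalizeSlice <- function(slice) {
  stopifnot(is(slice, "SliceImage"))
  p <- slice@pixels
  s <- stats::sd(p)
  if (!is.finite(s) || s == 0) {
    warning("constant slice: returning all zeros")
    p[] <- 0
  } else {
    p <- (p - mean(p)) / s
  }
  initialize(slice, pixels = p)
}

#' Side-view projection of a volume
#'
#' Averages `nAdjacent` adjacent side-view planes centered on the volume
#' midplane, the standard way to visualize a cell's vertical extent for
#' manual thickness measurement (e.g. averaging 513 adjacent YZ planes).
#' `"YZ"` averages along x and returns a (z, y) image; `"XZ"` averages along
#' y and returns a (z, x) image.
#'
#' @param volume a [TomoVolume-class].
#' @param axis `"YZ"` or `"XZ"`.
#' @param nAdjacent odd number of planes to average, at most the extent of
#'   the averaged axis.
#' @return A [SliceImage-class].
#' @export
projectSide <- function(volume, axis = c("YZ", "XZ"), nAdjacent = 1L) {
  stopifnot(is(volume, "TomoVolume"))
  axis <- match.arg(axis)
  d <- dim(volume@voxels)            # (z, y, x)
  extent <- if (axis == "YZ") d[3] else d[2]
  if (nAdjacent < 1L || nAdjacent %% 2L != 1L)
    stop("nAdjacent must be an odd positive integer")
  if (nAdjacent > extent)
    stop(sprintf("nAdjacent (%d) exceeds the %s extent (%d)",
                 nAdjacent, if (axis == "YZ") "x" else "y", extent))
  h <- (nAdjacent - 1L) %/% 2L
  mid <- (extent - 1L) %/% 2L + 1L   # 1-based center plane
  lo <- min(max(mid - h, 1L), extent - nAdjacent + 1L)
  idx <- lo + seq_len(nAdjacent) - 1L
  img <- if (axis == "YZ") {
    if (length(idx) == 1L) array(volume@voxels[, , idx], d[1:2])
    else apply(volume@voxels[, , idx, drop = FALSE], c(1, 2), mean)
  } else {
    if (length(idx) == 1L) array(volume@voxels[, idx, ], d[c(1, 3)])
    else apply(volume@voxels[, idx, , drop = FALSE], c(1, 3), mean)
  }
  new("SliceImage", pixels = img, apix = volume@apix)
}
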