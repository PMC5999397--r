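# Minimal MRC2014 volume I/O (mode 2, float32, little-endian). Only the
# header fields the pipeline needs are interpreted; the voxel size is taken
# from cella/mx as usual.

.MRC_HEADER_BYTES <- 1024L

#' Read an MRC2014 volume
#'
#' Reads a mode-2 (float32) MRC2014 file into a \linkS4class{TomoVolume}.
#' Axis order is normalized so the array is indexed \code{[x, y, z]} with z
#' along the beam. If the header voxel size is missing (zero cell), the
#' value given in \code{fallbackVoxelSize} is used with a warning.
#'
#' @param path file path.
#' @param fallbackVoxelSize voxel size in ångström to use when the header
#'   carries none.
#' @param bin integer block-binning factor applied after reading (1 = none).
#' @return A \linkS4class{TomoVolume}.
#' @export
readMRC <- function(path, fallbackVoxelSize = NULL, bin = 1L) {
  con <- file(path, "rb")
  on.exit(close(con))
  nxyz <- readBin(con, "integer", 3, size = 4, endian = "little")
  mode <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (any(nxyz <= 0) || any(nxyz > 1e5) || !mode %in% c(0L, 1L, 2L))
    stop("not a readable MRC file (bad dimensions or mode): ", path)
  invisible(readBin(con, "integer", 3, size = 4, endian = "little")) # nstart
  mxyz <- readBin(con, "integer", 3, size = 4, endian = "little")
  cella <- readBin(con, "numeric", 3, size = 4, endian = "little")
  invisible(readBin(con, "numeric", 3, size = 4, endian = "little")) # cellb
  mapcrs <- readBin(con, "integer", 3, size = 4, endian = "little")
  seek(con, 208)
  magic <- readBin(con, "raw", 4)
  if (!identical(magic[1:3], charToRaw("MAP")))
    stop("corrupt MRC header: missing MAP magic in ", path)
  seek(con, .MRC_HEADER_BYTES)
  n <- prod(nxyz)
  dat <- switch(as.character(mode),
    "0" = readBin(con, "integer", n, size = 1, signed = TRUE, endian = "little"),
    "1" = readBin(con, "integer", n, size = 2, signed = TRUE, endian = "little"),
    "2" = readBin(con, "numeric", n, size = 4, endian = "little"))
  if (length(dat) != n) stop("truncated MRC data in ", path)
  arr <- array(as.numeric(dat), dim = nxyz)
  if (!identical(mapcrs, c(1L, 2L, 3L)))
    arr <- aperm(arr, order(mapcrs))
  vs <- if (all(mxyz > 0) && all(cella > 0)) cella[1] / mxyz[1] else 0
  if (vs <= 0) {
    if (is.null(fallbackVoxelSize))
      stop("MRC header carries no voxel size and no fallback was given: ", path)
    warning("MRC header carries no voxel size; using fallback ",
            fallbackVoxelSize, " A")
    vs <- fallbackVoxelSize
  }
  vol <- TomoVolume(arr, vs)
  if (bin > 1L) vol <- binVolume(vol, as.integer(bin)) else vol
}

#' Write a TomoVolume as MRC2014
#'
#' Writes mode 2 (float32) with the voxel size recorded in the cell
#' dimensions, as produced by standard tomography packages.
#'
#' @param vol a \linkS4class{TomoVolume}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeMRC <- function(vol, path) {
  arr <- densities(vol)
  d <- dim(arr)
  con <- file(path, "wb")
  on.exit(close(con))
  wInt <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wFlt <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wInt(d)                       # nx ny nz
  wInt(2L)                      # mode 2 = float32
  wInt(c(0L, 0L, 0L))           # nxstart
  wInt(d)                       # mx my mz
  wFlt(d * voxelSize(vol))      # cella (Angstrom)
  wFlt(c(90, 90, 90))           # cellb
  wInt(c(1L, 2L, 3L))           # mapc mapr maps
  wFlt(c(min(arr), max(arr), mean(arr)))  # dmin dmax dmean
  wInt(1L)                      # ispg = 1 (volume)
  wInt(0L)                      # nsymbt
  writeBin(raw(100), con)       # extra
  wFlt(c(0, 0, 0))              # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wFlt(stats::sd(arr))          # rms
  wInt(1L)                      # nlabl
  lab <- sprintf("%-80s", "iceProfiler synthetic/processed volume")
  writeChar(substr(lab, 1, 80), con, nchars = 80, eos = NULL)
  writeBin(raw(9 * 80), con)
  wFlt(arr)
  invisible(path)
}

#' Block-bin a volume
#'
#' Reduces each axis by an integer factor by block averaging, multiplying
#' the voxel size accordingly (tomograms are conventionally analysed binned
#' by four). Trailing voxels that do not fill a block are dropped.
#'
#' @param vol a \linkS4class{TomoVolume}.
#' @param factor integer binning factor.
#' @return A binned \linkS4class{TomoVolume}.
#' @export
binVolume <- function(vol, factor = 4L) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1L)
  if (factor == 1L) return(vol)
  arr <- densities(vol)
  d <- dim(arr) %/% factor
  if (any(d < 1L)) stop("binning factor larger than the volume")
  arr <- arr[seq_len(d[1] * factor), seq_len(d[2] * factor),
             seq_len(d[3] * factor)]
  dim(arr) <- c(factor, d[1], factor, d[2], factor, d[3])
  out <- colMeans(arr)                       # (d1, f, d2, f, d3)
  out <- colMeans(aperm(out, c(2, 1, 3, 4, 5)))   # (d1, d2, f, d3)
  out <- colMeans(aperm(out, c(3, 1, 2, 4)))      # (d1, d2, d3)
  TomoVolume(out, voxelSize(vol) * factor)
}
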