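# Minimal MRC-2014 volume I/O (mode 2, 32-bit float), little-endian.
# Only what FSC work needs: dimensions, mode, and the voxel size derived from
# the cell dimensions; all other header words are written as standard
# defaults and ignored on read.

#' Read an MRC volume
#'
#' Supports mode 2 (32-bit float) volumes. The voxel size is taken from the
#' header cell dimensions divided by the grid size, as RELION and Warp write
#' it.
#'
#' @param path path to an `.mrc` file.
#' @return an `mrc_volume`: a list with `data` (3D numeric array) and
#'   `pixel_size` (Angstrom per voxel).
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 10L, size = 4L, endian = "little")
  nx <- hdr_int[1L]; ny <- hdr_int[2L]; nz <- hdr_int[3L]
  mode <- hdr_int[4L]
  if (mode != 2L) stop("only MRC mode 2 (float32) is supported, got mode ", mode)
  cell <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  seek(con, where = 92L)
  nsymbt <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  seek(con, where = 1024L + nsymbt)
  vals <- readBin(con, "numeric", n = nx * ny * nz, size = 4L, endian = "little")
  if (length(vals) != nx * ny * nz) stop("truncated MRC data block: ", path)
  px <- if (nx > 0 && cell[1L] > 0) cell[1L] / nx else 1
  structure(list(data = array(vals, dim = c(nx, ny, nz)), pixel_size = px),
            class = "mrc_volume")
}

#' Write an MRC volume
#'
#' Writes a mode-2 (float32) MRC-2014 file with the cell dimensions set to
#' `dim * pixel_size` so that readers recover the voxel size.
#'
#' @param vol 3D numeric array or an `mrc_volume`.
#' @param path output path.
#' @param pixel_size Angstrom per voxel (ignored if `vol` is an `mrc_volume`).
#' @return `path`, invisibly.
#' @export
write_mrc <- function(vol, path, pixel_size = 1) {
  if (inherits(vol, "mrc_volume")) {
    pixel_size <- vol$pixel_size
    vol <- vol$data
  }
  stopifnot(is.array(vol), length(dim(vol)) == 3L, pixel_size > 0)
  d <- dim(vol)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(d)                      # nx ny nz
  wi(2L)                     # mode 2
  wi(c(0L, 0L, 0L))          # nxstart..
  wi(d)                      # mx my mz
  wf(d * pixel_size)         # cell lengths (A)
  wf(c(90, 90, 90))          # cell angles
  wi(c(1L, 2L, 3L))          # axis order
  wf(c(min(vol), max(vol), mean(vol)))  # dmin dmax dmean
  wi(c(1L, 0L))              # ispg, nsymbt
  wi(integer(25L))           # extra
  wf(c(0, 0, 0))             # origin
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian machine stamp
  wf(stats::sd(vol))         # rms
  wi(0L)                     # nlabl
  writeBin(raw(800L), con)   # labels
  wf(vol)
  invisible(path)
}
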