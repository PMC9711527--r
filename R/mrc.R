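#' Read an MRC image, stack or volume (mode 2, 32-bit float)
#'
#' Minimal reader for the MRC2014 format as used for cryo-EM images and maps.
#' Only mode 2 (float32) is supported, which covers aligned sums, maximum
#' intensity projections and template volumes written by this package.
#'
#' @param path Path to an `.mrc` file.
#' @return A list with `data` (matrix for a single image, 3D array for a
#'   stack/volume, dimensions `[row, col, section]`) and `pixel_size`
#'   (Angstrom per pixel).
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdr[1]; ny <- hdr[2]; nz <- hdr[3]; mode <- hdr[4]
  if (mode != 2L) stop("only MRC mode 2 (float32) is supported")
  seek(con, 40)
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  pixel_size <- if (nx > 0 && cella[1] > 0) cella[1] / nx else 1
  seek(con, 92)
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  seek(con, 1024 + nsymbt)
  raw <- readBin(con, "numeric", n = nx * ny * nz, size = 4, endian = "little")
  # MRC rows are x-fastest; map to R matrices as [row = y, col = x]
  arr <- array(raw, dim = c(nx, ny, nz))
  arr <- aperm(arr, c(2, 1, 3))
  if (nz == 1L) arr <- arr[, , 1]
  list(data = arr, pixel_size = pixel_size)
}

#' Write an MRC image, stack or volume (mode 2)
#'
#' @param data Matrix (single image) or 3D array `[row, col, section]`.
#' @param path Output path.
#' @param pixel_size Pixel size in Angstrom, stored in the cell dimensions.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(data, path, pixel_size = 1) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  ny <- dim(data)[1]; nx <- dim(data)[2]; nz <- dim(data)[3]
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(c(nx, ny, nz, 2L, 0L, 0L, 0L, nx, ny, nz))          # words 1-10
  wf(c(nx, ny, nz) * pixel_size)                          # cella
  wf(c(90, 90, 90))                                       # cellb
  wi(c(1L, 2L, 3L))                                       # map order
  wf(c(min(data), max(data), mean(data)))                 # dmin/dmax/dmean
  wi(c(1L, 0L))                                           # ispg, nsymbt
  writeBin(raw(100), con)                                 # extra
  wf(c(0, 0, 0))                                          # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)        # little-endian stamp
  wf(stats::sd(as.vector(data)))                          # rms
  wi(0L)                                                  # nlabl
  writeBin(raw(800), con)                                 # labels
  writeBin(as.numeric(aperm(data, c(2, 1, 3))), con, size = 4,
           endian = "little")
  invisible(path)
}
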