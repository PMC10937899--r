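# Minimal MRC2014 reader/writer for 2-D micrographs. Data are stored with
# the x (column) axis fastest; in R the pixel matrix is (rows = y,
# columns = x), so the raster is transposed on the way in and out.

MRC_MODES <- c(`0` = "int8", `1` = "int16", `2` = "float32", `6` = "uint16")

#' Read a 2-D MRC micrograph
#'
#' Supports modes 0 (int8), 1 (int16), 2 (float32) and 6 (uint16); values
#' are returned as a float matrix. Stacks and volumes (`nz > 1`) are
#' rejected explicitly.
#'
#' @param path Path to an MRC file.
#' @return A [cryo_micrograph()]; `pixel_size` is taken from the cell
#'   dimensions when present.
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("MRC file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdr[1]; ny <- hdr[2]; nz <- hdr[3]; mode <- hdr[4]
  mx <- hdr[8]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  if (nx < 1 || ny < 1 || nx > 1e6 || ny > 1e6 || !(mode %in% c(0L, 1L, 2L, 6L)))
    stop("corrupt or unsupported MRC header in ", path,
         " (nx=", nx, ", ny=", ny, ", mode=", mode, ")")
  if (nz > 1)
    stop("unsupported dimensionality: ", path, " is a 3-D stack/volume (nz=",
         nz, "); only single 2-D micrographs are supported")
  seek(con, 1024)
  n <- nx * ny
  data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    "6" = as.numeric(readBin(con, "integer", n = n, size = 2, signed = FALSE,
                             endian = "little"))
  )
  if (length(data) < n) stop("truncated MRC data in ", path)
  if (!all(is.finite(data))) stop("non-finite pixel values in ", path)
  px <- t(matrix(data, nrow = nx, ncol = ny))
  ps <- if (mx > 0 && cella[1] > 0) cella[1] / mx else NA_real_
  cryo_micrograph(px, name = sub("\\.mrc$", "", basename(path)), pixel_size = ps)
}

#' Write a micrograph as a mode-2 (float32) MRC file
#'
#' @param micrograph A [cryo_micrograph()] (or plain matrix).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mrc <- function(micrograph, path) {
  if (is.matrix(micrograph)) micrograph <- cryo_micrograph(micrograph)
  px <- micrograph$pixels
  ny <- nrow(px); nx <- ncol(px)
  ps <- if (is.na(micrograph$pixel_size)) 1 else micrograph$pixel_size
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write MRC file: ", path))
  on.exit(close(con))
  writeBin(as.integer(c(nx, ny, 1, 2, 0, 0, 0, nx, ny, 1)), con, size = 4,
           endian = "little")
  writeBin(c(nx * ps, ny * ps, ps), con, size = 4, endian = "little")  # cella
  writeBin(c(90, 90, 90), con, size = 4, endian = "little")            # cellb
  writeBin(as.integer(c(1, 2, 3)), con, size = 4, endian = "little")   # axis order
  writeBin(c(min(px), max(px), mean(px)), con, size = 4, endian = "little")
  writeBin(as.integer(c(0, 0)), con, size = 4, endian = "little")      # ispg, nsymbt
  writeBin(raw(25 * 4), con)                                           # extra
  writeBin(numeric(3), con, size = 4, endian = "little")               # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)                     # little-endian stamp
  writeBin(as.numeric(stats::sd(px)), con, size = 4, endian = "little")
  writeBin(as.integer(0), con, size = 4, endian = "little")            # nlabl
  writeBin(raw(800), con)
  writeBin(as.vector(t(px)), con, size = 4, endian = "little")
  invisible(path)
}

#' Write a micrograph preview as PNG
#'
#' Linear min-max contrast stretch to 8-bit.
#'
#' @param micrograph A [cryo_micrograph()] or matrix.
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
write_png_preview <- function(micrograph, path) {
  if (inherits(micrograph, "cryo_micrograph")) micrograph <- micrograph$pixels
  rng <- range(micrograph)
  m <- if (diff(rng) > 0) (micrograph - rng[1]) / diff(rng) else micrograph * 0
  png::writePNG(m, path)
  invisible(path)
}
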