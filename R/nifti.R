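# Minimal self-contained NIfTI-1 single-file (.nii / .nii.gz) I/O for the
# package's grids. Only the fields this package produces/consumes are
# honoured: dim, datatype, pixdim, vox_offset, scl_slope/inter.
# Acquisition metadata that NIfTI does not carry (PE axis, polarity) goes in
# a JSON sidecar.

.niftiDatatypes <- c("uint8" = 2L, "int16" = 4L, "int32" = 8L,
                     "float32" = 16L, "float64" = 64L)
.niftiBitpix <- c("2" = 8L, "4" = 16L, "8" = 32L, "16" = 32L, "64" = 64L)

#' Write a 3-D or 4-D array as NIfTI-1
#'
#' Single-file NIfTI-1 (magic \code{n+1}), float64 data, little-endian;
#' gzip-compressed when the path ends in \code{.gz}.
#'
#' @param data numeric 3-D or 4-D array.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @param voxelSize mm per voxel (length 1 or 3).
#' @param TR repetition time (s), stored in pixdim for 4-D data.
#' @return \code{path}, invisibly.
#' @export
writeNifti <- function(data, path, voxelSize = 2.5, TR = 1) {
  d <- dim(data)
  stopifnot(length(d) %in% c(3L, 4L))
  vs <- rep(voxelSize, length.out = 3)
  pix <- c(0, vs, if (length(d) == 4L) TR else 1, 1, 1, 1)
  hdr <- raw(348)
  put <- function(hdr, off, val, what, size) {
    b <- writeBin(val, raw(), size = size, endian = "little")
    hdr[(off + 1):(off + length(b))] <- b
    hdr
  }
  hdr <- put(hdr, 0, 348L, "int", 4)
  hdr <- put(hdr, 40, as.integer(c(length(d), d, rep(1L, 7 - length(d)))), "int", 2)
  hdr <- put(hdr, 70, 64L, "int", 2)        # datatype float64
  hdr <- put(hdr, 72, 64L, "int", 2)        # bitpix
  hdr <- put(hdr, 76, as.numeric(pix), "dbl", 4)
  hdr <- put(hdr, 108, 352, "dbl", 4)       # vox_offset
  hdr <- put(hdr, 112, c(1, 0), "dbl", 4)   # scl_slope, scl_inter
  hdr <- put(hdr, 344, c(charToRaw("n+1"), as.raw(0)), "raw", 1)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4), con)                     # extension flag
  writeBin(as.numeric(data), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Reads single-file little-endian NIfTI-1 with scalar datatypes; applies
#' \code{scl_slope}/\code{scl_inter} when set.
#'
#' @param path a \code{.nii} or \code{.nii.gz} file.
#' @return List with \code{data} (array), \code{voxelSize} (mm, length 3)
#'   and \code{TR} (s, for 4-D data).
#' @export
readNifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, raw(), n = 348)
  geti <- function(off, n, size) readBin(hdr[(off + 1):(off + n * size)],
                                         integer(), n = n, size = size,
                                         endian = "little")
  getf <- function(off, n) readBin(hdr[(off + 1):(off + n * 4)], numeric(),
                                   n = n, size = 4, endian = "little")
  if (geti(0, 1, 4) != 348) stop("not a little-endian NIfTI-1 file")
  dims <- geti(40, 8, 2)
  nd <- dims[1]
  d <- dims[2:(1 + nd)]
  datatype <- geti(70, 1, 2)
  pix <- getf(76, 8)
  voxOffset <- getf(108, 1)
  slope <- getf(112, 1)
  inter <- getf(116, 1)
  skip <- voxOffset - 348
  if (skip > 0) readBin(con, raw(), n = skip)
  n <- prod(d)
  vals <- switch(as.character(datatype),
    "2" = as.numeric(readBin(con, integer(), n = n, size = 1, signed = FALSE)),
    "4" = as.numeric(readBin(con, integer(), n = n, size = 2, endian = "little")),
    "8" = as.numeric(readBin(con, integer(), n = n, size = 4, endian = "little")),
    "16" = readBin(con, numeric(), n = n, size = 4, endian = "little"),
    "64" = readBin(con, numeric(), n = n, size = 8, endian = "little"),
    stop("unsupported NIfTI datatype: ", datatype))
  if (slope != 0 && !(slope == 1 && inter == 0)) vals <- vals * slope + inter
  list(data = array(vals, d), voxelSize = pix[2:4],
       TR = if (nd == 4L) pix[5] else NA_real_)
}

#' Write/read the acquisition sidecar
#'
#' NIfTI does not carry the PE axis or polarity, so geometry goes in a JSON
#' sidecar next to the image.
#'
#' @param geom an \linkS4class{EPIGeometry}.
#' @param path sidecar path (conventionally \code{<image>.json}).
#' @return \code{writeGeometry}: the path, invisibly; \code{readGeometry}:
#'   an \linkS4class{EPIGeometry}.
#' @export
writeGeometry <- function(geom, path) {
  jsonlite::write_json(list(
    voxelSizePE = geom@voxelSizePE, nPE = geom@nPE,
    echoSpacing = geom@echoSpacing, accel = geom@accel,
    peAxis = geom@peAxis, pePolarity = geom@pePolarity),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeGeometry
#' @export
readGeometry <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  EPIGeometry(voxelSizePE = j$voxelSizePE, nPE = j$nPE,
              echoSpacing = j$echoSpacing, accel = j$accel,
              peAxis = j$peAxis, pePolarity = j$pePolarity)
}
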