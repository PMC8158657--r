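# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# Supports the subset of the format the pipeline needs: 3D volumes, scalar
# datatypes uint8/int16/int32/float32/float64, spacing from pixdim, and the
# sform affine for consistency checks. Both endiannesses are read; files are
# written little-endian with vox_offset 352 and magic "n+1".

NIFTI_TYPES <- list(
  `2` = list(what = "integer", size = 1L, signed = FALSE, bitpix = 8L),
  `4` = list(what = "integer", size = 2L, signed = TRUE, bitpix = 16L),
  `8` = list(what = "integer", size = 4L, signed = TRUE, bitpix = 32L),
  `16` = list(what = "double", size = 4L, signed = TRUE, bitpix = 32L),
  `64` = list(what = "double", size = 8L, signed = TRUE, bitpix = 64L)
)

read_file_raw <- function(path) {
  con <- gzfile(path, "rb") # transparently handles uncompressed files too
  on.exit(close(con))
  chunks <- list()
  repeat {
    ch <- readBin(con, "raw", n = 1048576L)
    if (length(ch) == 0L) break
    chunks[[length(chunks) + 1L]] <- ch
  }
  do.call(c, chunks)
}

#' Read a NIfTI-1 volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with `img` (numeric array), `spacing` (voxel size per axis,
#'   mm), and `header` (parsed fields including the sform rows).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  raw <- read_file_raw(path)
  if (length(raw) < 352L) stop("file too short for a NIfTI-1 header: ", path)
  rint <- function(off, size, n, endian, signed = TRUE) {
    readBin(raw[(off + 1L):(off + size * n)], "integer",
      n = n, size = size, endian = endian, signed = signed
    )
  }
  rflt <- function(off, n, endian) {
    readBin(raw[(off + 1L):(off + 4L * n)], "double",
      n = n, size = 4L, endian = endian
    )
  }
  endian <- "little"
  if (rint(0L, 4L, 1L, "little") != 348L) {
    endian <- "big"
    if (rint(0L, 4L, 1L, "big") != 348L) {
      stop("not a NIfTI-1 file (sizeof_hdr != 348): ", path)
    }
  }
  magic <- rawToChar(raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("bad NIfTI magic in ", path)
  dims <- rint(40L, 2L, 8L, endian)
  nd <- dims[1]
  if (nd < 3L) stop("expected a 3D volume in ", path)
  shape <- dims[2:4]
  if (nd > 3L && any(dims[5:(nd + 1L)] > 1L)) {
    stop("only scalar 3D volumes are supported: ", path)
  }
  datatype <- rint(70L, 2L, 1L, endian)
  tp <- NIFTI_TYPES[[as.character(datatype)]]
  if (is.null(tp)) stop("unsupported NIfTI datatype code ", datatype)
  pixdim <- rflt(76L, 8L, endian)
  vox_offset <- rflt(108L, 1L, endian)
  scl_slope <- rflt(112L, 1L, endian)
  scl_inter <- rflt(116L, 1L, endian)
  sform_code <- rint(254L, 2L, 1L, endian)
  srow <- rbind(
    rflt(280L, 4L, endian),
    rflt(296L, 4L, endian),
    rflt(312L, 4L, endian)
  )
  nvox <- prod(shape)
  off <- as.integer(round(vox_offset))
  dat <- readBin(raw[(off + 1L):(off + tp$size * nvox)], tp$what,
    n = nvox, size = tp$size, endian = endian, signed = tp$signed
  )
  img <- array(as.double(dat), dim = shape)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    img <- img * scl_slope + scl_inter
  }
  list(
    img = img,
    spacing = abs(pixdim[2:4]),
    header = list(
      datatype = datatype, pixdim = pixdim, sform_code = sform_code,
      srow = srow, endian = endian
    )
  )
}

#' Write a NIfTI-1 volume
#'
#' @param img 3D numeric array.
#' @param path Output path; gzip-compressed when it ends in `.gz`.
#' @param spacing Voxel size per axis in mm.
#' @param datatype NIfTI datatype code: 2 (uint8), 4 (int16), 8 (int32),
#'   16 (float32, default) or 64 (float64).
#' @return Invisibly, `path`.
#' @export
write_nifti <- function(img, path, spacing = c(1, 1, 1), datatype = 16L) {
  stopifnot(length(dim(img)) == 3L)
  tp <- NIFTI_TYPES[[as.character(datatype)]]
  if (is.null(tp)) stop("unsupported NIfTI datatype code ", datatype)
  shape <- dim(img)
  hdr <- raw(348L)
  con <- rawConnection(hdr, "r+")
  wi <- function(x, off, size) {
    seek(con, off)
    writeBin(as.integer(x), con, size = size, endian = "little")
  }
  wf <- function(x, off) {
    seek(con, off)
    writeBin(as.double(x), con, size = 4L, endian = "little")
  }
  wi(348L, 0L, 4L)
  wi(c(3L, shape, 1L, 1L, 1L, 1L), 40L, 2L)
  wi(datatype, 70L, 2L)
  wi(tp$bitpix, 72L, 2L)
  wf(c(1, spacing, 0, 0, 0, 0), 76L)
  wf(352, 108L) # vox_offset
  wf(1, 112L) # scl_slope
  wf(0, 116L) # scl_inter
  wi(0L, 252L, 2L) # qform_code
  wi(1L, 254L, 2L) # sform_code
  wf(c(spacing[1], 0, 0, 0), 280L)
  wf(c(0, spacing[2], 0, 0), 296L)
  wf(c(0, 0, spacing[3], 0), 312L)
  seek(con, 344L)
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)
  hdr <- rawConnectionValue(con)
  close(con)

  out <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(out))
  writeBin(hdr, out)
  writeBin(raw(4L), out) # extension flag, pads header to vox_offset 352
  vals <- as.vector(img)
  if (tp$what == "integer") {
    writeBin(as.integer(round(vals)), out, size = tp$size, endian = "little")
  } else {
    writeBin(as.double(vals), out, size = tp$size, endian = "little")
  }
  invisible(path)
}
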