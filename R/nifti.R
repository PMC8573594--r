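# Minimal NIfTI-1 I/O.
#
# The package only needs single-file (.nii / .nii.gz) 3D images with a
# diagonal affine: enough to exchange FLAIR/T1 volumes and masks with
# standard neuroimaging tools. Data are written as float32 (images) or uint8
# (masks); reading supports the datatypes this package and common upstream
# tools emit. This is deliberately not a general NIfTI implementation.

NIFTI_DT <- c(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L, float64 = 64L)
NIFTI_BITPIX <- c(uint8 = 8L, int16 = 16L, int32 = 32L, float32 = 32L, float64 = 64L)

#' Write a 3D volume as NIfTI-1
#'
#' @param volume numeric 3D array.
#' @param path output path; compressed with gzip when it ends in `.gz`.
#' @param pixdim voxel dimensions in mm (length 3).
#' @param datatype `"float32"` (default) or `"uint8"` (for masks).
#' @return `path`, invisibly.
#' @export
nifti_write <- function(volume, path, pixdim = c(1, 1, 1),
                        datatype = c("float32", "uint8")) {
  datatype <- match.arg(datatype)
  stopifnot(length(dim(volume)) == 3, length(pixdim) == 3)
  d <- dim(volume)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size = 4) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(348)                                   # sizeof_hdr
  writeBin(raw(36), con)                    # unused (data_type..dim_info)
  wi(c(3, d, 1, 1, 1, 1), size = 2)         # dim[8]
  wf(c(0, 0, 0))                            # intent_p1..p3
  wi(0, size = 2)                           # intent_code
  wi(NIFTI_DT[[datatype]], size = 2)        # datatype
  wi(NIFTI_BITPIX[[datatype]], size = 2)    # bitpix
  wi(0, size = 2)                           # slice_start
  wf(c(1, pixdim, 1, 1, 1, 1))              # pixdim[8] (qfac = 1)
  wf(352)                                   # vox_offset
  wf(1); wf(0)                              # scl_slope, scl_inter
  wi(0, size = 2); writeBin(raw(2), con)    # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0))                            # cal_max, cal_min, slice_duration
  wf(0)                                     # toffset
  wi(c(0, 0))                               # glmax, glmin
  writeBin(raw(104), con)                   # descrip + aux_file
  wi(c(0, 1), size = 2)                     # qform_code = 0, sform_code = 1
  wf(rep(0, 6))                             # quatern b,c,d + qoffset x,y,z
  wf(c(pixdim[1], 0, 0, 0))                 # srow_x
  wf(c(0, pixdim[2], 0, 0))                 # srow_y
  wf(c(0, 0, pixdim[3], 0))                 # srow_z
  writeBin(raw(16), con)                    # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)  # magic
  writeBin(raw(4), con)                     # extension flag
  if (datatype == "uint8") {
    writeBin(as.raw(round(pmin(pmax(volume, 0), 255))), con)
  } else {
    writeBin(as.numeric(volume), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume written by this package or compatible tools
#'
#' Supports single-file little-endian NIfTI-1 with 3D data and the datatypes
#' uint8/int16/int32/float32/float64; applies `scl_slope`/`scl_inter` when
#' set.
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return list with `data` (3D array) and `pixdim` (length-3 numeric).
#' @export
nifti_read <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  ri <- function(n, size = 4) readBin(con, "integer", n, size = size, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  hdr_size <- ri(1)
  if (!identical(hdr_size, 348L)) stop("not a little-endian NIfTI-1 file: ", path)
  readBin(con, "raw", 36)
  dims <- ri(8, size = 2)
  if (dims[1] < 3) stop("expected 3D image")
  d <- dims[2:4]
  rf(3); ri(1, size = 2)
  dtype <- ri(1, size = 2)
  ri(1, size = 2); ri(1, size = 2)          # bitpix, slice_start
  pixdim <- rf(8)[2:4]
  vox_offset <- rf(1)
  scl_slope <- rf(1); scl_inter <- rf(1)
  skip <- max(vox_offset, 352) - 120        # rest of the header + extensions
  readBin(con, "raw", skip)
  nvox <- prod(d)
  data <- switch(as.character(dtype),
    "2"  = as.numeric(readBin(con, "integer", nvox, size = 1, signed = FALSE)),
    "4"  = as.numeric(readBin(con, "integer", nvox, size = 2, endian = "little")),
    "8"  = as.numeric(readBin(con, "integer", nvox, size = 4, endian = "little")),
    "16" = readBin(con, "numeric", nvox, size = 4, endian = "little"),
    "64" = readBin(con, "numeric", nvox, size = 8, endian = "little"),
    stop("unsupported NIfTI datatype code: ", dtype))
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  list(data = array(data, dim = d), pixdim = pixdim)
}
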