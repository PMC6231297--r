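# Minimal NIfTI-1 single-file (.nii / .nii.gz) support.
#
# Only what the pipeline needs: 3D volumes, the standard 348-byte header,
# datatypes uint8/int8/int16/uint16/int32/float32/float64, scl_slope/scl_inter
# scaling, and both endiannesses on read. Written files are little-endian
# float64 (lossless round-trip) or int16 for integer-valued data.

NIFTI_DATATYPES <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "numeric", size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "numeric", size = 8L, signed = TRUE),   # float64
  `256` = list(what = "integer", size = 1L, signed = TRUE),   # int8
  `512` = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

nifti_connection <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a 3D NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (`.nii` or `.nii.gz`) into a plain
#' numeric 3D array. Both little- and big-endian files are handled;
#' `scl_slope`/`scl_inter` scaling is applied when set. Trailing singleton
#' dimensions (e.g. a degenerate 4th dimension of length 1) are dropped;
#' genuinely higher-dimensional images are an error.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return Numeric 3D array with attribute `pixdim` (voxel sizes, mm).
#' @seealso [write_nifti()], [read_volume()]
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  con <- nifti_connection(path, "rb")
  on.exit(close(con))

  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header in ", path)

  endian <- "little"
  sizeof_hdr <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }

  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("unsupported NIfTI magic '", magic, "' in ", path)
  if (magic == "ni1") stop("two-file NIfTI (.hdr/.img) not supported: ", path)

  dims <- readBin(hdr[41:56], "integer", n = 8L, size = 2L, endian = endian)
  ndim <- dims[1]
  if (ndim < 1L || ndim > 7L) stop("corrupt NIfTI dim[0] = ", ndim)
  shape <- dims[2:(1 + ndim)]
  if (ndim < 3L) stop("volume in ", path, " is ", ndim, "D; a 3D volume is required")
  if (ndim > 3L && prod(shape[4:ndim]) != 1L)
    stop("volume in ", path, " is ", ndim, "D; a 3D volume is required")
  shape <- shape[1:3]
  if (any(shape <= 0L)) stop("non-positive dimension in NIfTI header of ", path)

  datatype <- readBin(hdr[71:72], "integer", size = 2L, endian = endian)
  dt <- NIFTI_DATATYPES[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype, " in ", path)

  pixdim <- readBin(hdr[77:108], "numeric", n = 8L, size = 4L, endian = endian)[2:4]
  vox_offset <- readBin(hdr[109:112], "numeric", size = 4L, endian = endian)
  scl_slope <- readBin(hdr[113:116], "numeric", size = 4L, endian = endian)
  scl_inter <- readBin(hdr[117:120], "numeric", size = 4L, endian = endian)

  skip <- as.integer(round(vox_offset)) - 348L
  if (skip < 0L) stop("invalid vox_offset ", vox_offset, " in ", path)
  if (skip > 0L) readBin(con, "raw", n = skip)

  n <- prod(shape)
  data <- readBin(con, dt$what, n = n, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(data) < n) stop("truncated NIfTI data in ", path)
  data <- as.double(data)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter

  arr <- array(data, dim = shape)
  attr(arr, "pixdim") <- pixdim
  arr
}

#' Write a 3D array as a NIfTI-1 volume
#'
#' Writes a single-file little-endian NIfTI-1 image. Data are stored as
#' float64 by default so write/read round-trips are lossless; integer-valued
#' arrays within int16 range may be stored as int16 with `datatype = "int16"`.
#'
#' @param data Numeric 3D array.
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @param pixdim Voxel sizes in mm, length 3.
#' @param datatype `"float64"` (default) or `"int16"`.
#' @export
write_nifti <- function(data, path, pixdim = c(1, 1, 1), datatype = c("float64", "int16")) {
  datatype <- match.arg(datatype)
  if (length(dim(data)) != 3L) stop("write_nifti() requires a 3D array")
  shape <- dim(data)

  code <- if (datatype == "float64") 64L else 4L
  bitpix <- if (datatype == "float64") 64L else 16L
  if (datatype == "int16") {
    if (any(data != round(data)) || any(abs(data) > 32767))
      stop("data not representable as int16; use datatype = 'float64'")
  }

  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  end <- "little"
  wI <- function(x, size) writeBin(as.integer(x), con, size = size, endian = end)
  wF <- function(x, size) writeBin(as.double(x), con, size = size, endian = end)
  wRaw0 <- function(n) writeBin(raw(n), con)

  wI(348L, 4L)                                   # sizeof_hdr
  wRaw0(36L)                                     # data_type, db_name, extents, session_error, regular, dim_info
  wI(c(3L, shape, 1L, 1L, 1L, 1L), 2L)           # dim[0..7]
  wF(c(0, 0, 0), 4L)                             # intent_p1..p3
  wI(0L, 2L)                                     # intent_code
  wI(code, 2L)                                   # datatype
  wI(bitpix, 2L)                                 # bitpix
  wI(0L, 2L)                                     # slice_start
  wF(c(1, pixdim, 1, 1, 1, 1), 4L)               # pixdim[0..7]
  wF(352, 4L)                                    # vox_offset
  wF(1, 4L)                                      # scl_slope
  wF(0, 4L)                                      # scl_inter
  wI(0L, 2L)                                     # slice_end
  wRaw0(2L)                                      # slice_code, xyzt_units
  wF(c(0, 0, 0), 4L)                             # cal_max, cal_min, slice_duration
  wF(0, 4L)                                      # toffset
  wI(c(0L, 0L), 4L)                              # glmax, glmin
  wRaw0(104L)                                    # descrip(80) + aux_file(24)
  wI(c(0L, 0L), 2L)                              # qform_code, sform_code
  wF(rep(0, 6), 4L)                              # quatern_b..qoffset_z
  wF(rep(0, 12), 4L)                             # srow_x/y/z
  wRaw0(16L)                                     # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)     # magic
  wRaw0(4L)                                      # extension indicator
  if (datatype == "float64") wF(data, 8L) else wI(data, 2L)
  invisible(path)
}
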