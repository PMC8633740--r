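# Minimal NIfTI-1 reader/writer (single-file .nii / .nii.gz, float32 or
# float64 payload). No dedicated NIfTI package is available in this
# environment, so the 348-byte header is handled directly; only the fields
# this package needs are honoured (dim, pixdim incl. TR, datatype, scl_slope/
# scl_inter on read, magic "n+1").

NIFTI_FLOAT32 <- 16L
NIFTI_FLOAT64 <- 64L
NIFTI_INT16 <- 4L
NIFTI_UINT8 <- 2L

#' Write an array as a NIfTI-1 image
#'
#' Writes 3D or 4D numeric data as a single-file NIfTI-1 image (`.nii`, or
#' gzip-compressed when the path ends in `.nii.gz`). The repetition time of a
#' 4D series is recorded in `pixdim[4]` (seconds).
#'
#' @param data numeric array, 3 or 4 dimensions (logical masks are written as
#'   0/1 float data).
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param voxel_size_mm numeric length 3, voxel edges in mm.
#' @param tr_seconds repetition time stored for the 4th dimension.
#' @param datatype `"float32"` (default) or `"float64"`.
#' @return `path`, invisibly.
#' @seealso [read_nifti()]
#' @export
write_nifti <- function(data, path, voxel_size_mm = c(3, 3, 3), tr_seconds = 0,
                        datatype = c("float32", "float64")) {
  datatype <- match.arg(datatype)
  if (is.logical(data)) data <- array(as.numeric(data), dim = dim(data))
  nd <- length(dim(data))
  stopifnot(nd %in% c(3L, 4L))
  dm <- dim(data)
  dim_field <- rep(1L, 8)
  dim_field[1] <- nd
  dim_field[seq_len(nd) + 1] <- dm
  pixdim <- rep(0, 8)
  pixdim[2:4] <- voxel_size_mm
  pixdim[5] <- tr_seconds
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(348L, 4)                                   # sizeof_hdr
  writeBin(raw(35), con)                        # data_type, db_name, extents, session_error, regular
  writeBin(as.raw(0x30), con)                   # dim_info placeholder (ignored)
  wi(dim_field, 2)                              # dim[8]
  wf(c(0, 0, 0))                                # intent_p1..p3
  wi(0L, 2)                                     # intent_code
  wi(if (datatype == "float32") NIFTI_FLOAT32 else NIFTI_FLOAT64, 2)  # datatype
  wi(if (datatype == "float32") 32L else 64L, 2)  # bitpix
  wi(0L, 2)                                     # slice_start
  wf(pixdim)                                    # pixdim[8]
  wf(352)                                       # vox_offset
  wf(1)                                         # scl_slope
  wf(0)                                         # scl_inter
  wi(0L, 2); writeBin(raw(2), con)              # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0))                                # cal_max, cal_min, slice_duration
  wf(0)                                         # toffset
  wi(c(0L, 0L), 4)                              # glmax, glmin
  writeBin(raw(104), con)                       # descrip[80] + aux_file[24]
  wi(c(0L, 0L), 2)                              # qform_code, sform_code
  wf(rep(0, 18))                                # quatern/qoffset + srow_x/y/z
  writeBin(raw(16), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con) # magic
  writeBin(raw(4), con)                         # extension flag
  writeBin(as.numeric(data), con,
           size = if (datatype == "float32") 4 else 8, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 image
#'
#' Reads single-file NIfTI-1 images (optionally gzipped). Supports uint8,
#' int16, float32 and float64 payloads; `scl_slope`/`scl_inter` scaling is
#' applied when set.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return numeric array with attributes `voxel_size_mm` (length 3) and
#'   `tr_seconds` (scalar, 4D images).
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("not a NIfTI-1 file (short header): ", path)
  ri <- function(off, size, n = 1)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  rf <- function(off, n = 1)
    readBin(hdr[(off + 1):(off + 4 * n)], "double", n = n, size = 4,
            endian = "little")
  if (ri(0, 4) != 348L) stop("not a NIfTI-1 file (sizeof_hdr != 348): ", path)
  dim_field <- ri(40, 2, 8)
  nd <- dim_field[1]
  if (!nd %in% 1:4) stop("unsupported NIfTI dimensionality: ", nd)
  dm <- pmax(dim_field[seq_len(nd) + 1], 1L)
  datatype <- ri(70, 2)
  pixdim <- rf(76, 8)
  vox_offset <- rf(108)
  scl_slope <- rf(112)
  scl_inter <- rf(116)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  n <- prod(dm)
  data <- switch(as.character(datatype),
    "2"  = as.numeric(readBin(con, "integer", n = n, size = 1, signed = FALSE)),
    "4"  = as.numeric(readBin(con, "integer", n = n, size = 2, endian = "little")),
    "16" = readBin(con, "double", n = n, size = 4, endian = "little"),
    "64" = readBin(con, "double", n = n, size = 8, endian = "little"),
    stop("unsupported NIfTI datatype code: ", datatype))
  if (length(data) < n) stop("truncated NIfTI payload in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  out <- array(data, dim = dm)
  attr(out, "voxel_size_mm") <- pixdim[2:4]
  if (nd == 4L) attr(out, "tr_seconds") <- pixdim[5]
  out
}
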