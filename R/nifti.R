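# Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O for 2D images and masks.
#
# No NIfTI package is available in the supported dependency set, so a small
# writer/reader is provided here. It covers exactly what the pipeline needs:
# little-endian single-file NIfTI-1, 2D grids, float64 images (so Hounsfield
# values round-trip bit-exactly) and uint8 masks. The test suite cross-checks
# the format against an independent NIfTI implementation.

NIFTI_DT_UINT8 <- 2L
NIFTI_DT_FLOAT64 <- 64L

nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

write_nifti_chars <- function(con, s, width) {
  raw_s <- charToRaw(s)
  if (length(raw_s) > width) raw_s <- raw_s[seq_len(width)]
  writeBin(c(raw_s, raw(width - length(raw_s))), con)
}

#' Write a 2D image or mask as NIfTI-1
#'
#' Writes a single-file little-endian NIfTI-1 volume with one 2D grid.
#' Images are stored as float64 so pixel values round-trip exactly; masks
#' as uint8.
#'
#' @param pixels numeric or logical matrix (rows = first image axis).
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param spacing length-2 numeric, mm per pixel along (row, col).
#' @param datatype `"float64"` (default for images) or `"uint8"` (masks).
#' @return `path`, invisibly.
#' @seealso [read_nifti()]
#' @export
write_nifti <- function(pixels, path, spacing = c(1, 1),
                        datatype = c("float64", "uint8")) {
  stopifnot(is.matrix(pixels), length(spacing) == 2L, all(spacing > 0))
  datatype <- match.arg(datatype)
  dt <- if (datatype == "uint8") NIFTI_DT_UINT8 else NIFTI_DT_FLOAT64
  bitpix <- if (datatype == "uint8") 8L else 64L
  con <- nifti_open(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_i8 <- function(x) writeBin(as.integer(x), con, size = 1L)
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")

  w_i32(348L)                                   # sizeof_hdr
  writeBin(raw(28L), con)                       # data_type, db_name
  w_i32(0L)                                     # extents
  w_i16(0L)                                     # session_error
  w_i8(utf8ToInt("r"))                          # regular
  w_i8(0L)                                      # dim_info
  w_i16(c(2L, nrow(pixels), ncol(pixels), 1L, 1L, 1L, 1L, 1L))  # dim
  w_f32(c(0, 0, 0))                             # intent_p1..p3
  w_i16(0L)                                     # intent_code
  w_i16(dt)                                     # datatype
  w_i16(bitpix)                                 # bitpix
  w_i16(0L)                                     # slice_start
  w_f32(c(1, spacing[1], spacing[2], 1, 1, 1, 1, 1))  # pixdim
  w_f32(352)                                    # vox_offset
  w_f32(1)                                      # scl_slope
  w_f32(0)                                      # scl_inter
  w_i16(0L)                                     # slice_end
  w_i8(0L)                                      # slice_code
  w_i8(2L)                                      # xyzt_units: mm
  w_f32(c(0, 0, 0, 0))                          # cal_max..toffset
  w_i32(c(0L, 0L))                              # glmax, glmin
  write_nifti_chars(con, "noduletex", 80L)      # descrip
  writeBin(raw(24L), con)                       # aux_file
  w_i16(0L)                                     # qform_code
  w_i16(1L)                                     # sform_code
  w_f32(c(0, 0, 0))                             # quatern_b..d
  w_f32(c(0, 0, 0))                             # qoffset_x..z
  w_f32(c(spacing[1], 0, 0, 0))                 # srow_x
  w_f32(c(0, spacing[2], 0, 0))                 # srow_y
  w_f32(c(0, 0, 1, 0))                          # srow_z
  writeBin(raw(16L), con)                       # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  writeBin(raw(4L), con)                        # extension flag

  if (datatype == "uint8") {
    storage.mode(pixels) <- "integer"
    writeBin(as.integer(pixels), con, size = 1L)
  } else {
    writeBin(as.numeric(pixels), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' Read a 2D NIfTI-1 volume written by [write_nifti()]
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return list with `pixels` (matrix), `spacing` (length-2 numeric, mm) and
#'   `datatype`.
#' @export
read_nifti <- function(path) {
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 352L)
  if (length(hdr) < 348L) stop("not a NIfTI-1 file: header too short")
  r_i32 <- function(off) readBin(hdr[(off + 1):(off + 4)], "integer",
                                 size = 4L, endian = "little")
  r_i16 <- function(off, n = 1L) readBin(hdr[(off + 1):(off + 2L * n)],
                                         "integer", size = 2L, n = n,
                                         endian = "little")
  r_f32 <- function(off, n = 1L) readBin(hdr[(off + 1):(off + 4L * n)],
                                         "numeric", size = 4L, n = n,
                                         endian = "little")
  if (r_i32(0L) != 348L) stop("not a NIfTI-1 file: bad sizeof_hdr")
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file: bad magic")
  dim <- r_i16(40L, 8L)
  ndim <- dim[1]
  extent <- dim[2:(1 + max(ndim, 2L))]
  if (prod(extent[-(1:2)] %||% 1L) > 1) {
    stop("only single-slice (2D) NIfTI volumes are supported")
  }
  nx <- dim[2]
  ny <- dim[3]
  datatype <- r_i16(70L)
  pixdim <- r_f32(76L, 8L)
  vox_offset <- r_f32(108L)
  skip <- as.integer(vox_offset) - 352L
  if (skip > 0) readBin(con, "raw", n = skip)
  n <- as.integer(nx) * as.integer(ny)
  if (datatype == NIFTI_DT_UINT8) {
    vals <- as.integer(readBin(con, "integer", n = n, size = 1L, signed = FALSE))
    dtype <- "uint8"
  } else if (datatype == NIFTI_DT_FLOAT64) {
    vals <- readBin(con, "numeric", n = n, size = 8L, endian = "little")
    dtype <- "float64"
  } else if (datatype == 16L) {
    vals <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
    dtype <- "float32"
  } else {
    stop("unsupported NIfTI datatype code: ", datatype)
  }
  list(pixels = matrix(vals, nrow = nx, ncol = ny),
       spacing = pixdim[2:3], datatype = dtype)
}
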