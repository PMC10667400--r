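# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# Only what this pipeline needs: 3D volumes, data types uint8 (2), int16 (4),
# int32 (8), float32 (16), float64 (64), pixdim spacing, little-endian,
# no extensions. The environment ships no NIfTI package, so this is a
# deliberately small, round-trip-tested implementation rather than a general
# one.

nii_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a 3D volume as NIfTI-1
#'
#' @param volume 3D numeric or logical array.
#' @param path Output path (.nii or .nii.gz).
#' @param spacing Voxel spacing in mm (length 3).
#' @param datatype "float32" (default), "float64", "uint8", or "int16".
#' @return Invisibly, \code{path}.
#' @export
write_nifti <- function(volume, path, spacing = c(1, 1, 1),
                        datatype = c("float32", "float64", "uint8", "int16")) {
  datatype <- match.arg(datatype)
  stopifnot(length(dim(volume)) == 3, length(spacing) == 3)
  if (is.logical(volume)) volume <- array(as.integer(volume), dim(volume))
  dt <- switch(datatype,
               uint8 = list(code = 2L, bits = 8L, what = "integer", size = 1L),
               int16 = list(code = 4L, bits = 16L, what = "integer", size = 2L),
               float32 = list(code = 16L, bits = 32L, what = "double", size = 4L),
               float64 = list(code = 64L, bits = 64L, what = "double", size = 8L))
  con <- nii_open(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  wi(348L, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                        # data_type..db_name, extents..
  d <- dim(volume)
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2)               # dim[8]
  wf(c(0, 0, 0))                                # intent_p1..3
  wi(0L, 2)                                     # intent_code
  wi(dt$code, 2)                                # datatype
  wi(dt$bits, 2)                                # bitpix
  wi(0L, 2)                                     # slice_start
  wf(c(1, spacing, 1, 1, 1, 1))                 # pixdim[8] (qfac = 1)
  wf(352)                                       # vox_offset
  wf(1); wf(0)                                  # scl_slope, scl_inter
  wi(0L, 2); writeBin(raw(1), con); writeBin(raw(1), con) # slice_end/code/xyzt
  wf(c(0, 0, 0))                                # cal_max, cal_min, slice_dur
  wf(0)                                         # toffset
  wi(c(0L, 0L), 4)                              # glmax, glmin
  writeBin(raw(80 + 24), con)                   # descrip, aux_file
  wi(c(0L, 1L), 2)                              # qform_code, sform_code = 1
  wf(c(0, 0, 0, 0, 0, 0))                       # quaternions b,c,d + offsets
  wf(c(spacing[1], 0, 0, 0))                    # srow_x
  wf(c(0, spacing[2], 0, 0))                    # srow_y
  wf(c(0, 0, spacing[3], 0))                    # srow_z
  writeBin(raw(16), con)                        # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL)
  writeBin(raw(1), con)
  writeBin(raw(4), con)                         # extension flag
  v <- as.vector(volume)
  if (dt$what == "integer") {
    writeBin(as.integer(round(v)), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.double(v), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' Read a 3D NIfTI-1 volume
#'
#' @param path .nii or .nii.gz file.
#' @return 3D array with attribute \code{spacing} (mm).
#' @export
read_nifti <- function(path) {
  con <- nii_open(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  sz <- readBin(hdr[1:4], "integer", 1, size = 4, endian = "little")
  if (sz != 348) stop("not a little-endian NIfTI-1 file (sizeof_hdr = ", sz, ")")
  dimv <- readBin(hdr[41:56], "integer", 8, size = 2, endian = "little")
  ndim <- dimv[1]
  if (ndim != 3) {
    stop("expected a 3D volume, got ", ndim, "D with axes [",
         paste(dimv[2:(1 + max(ndim, 1))], collapse = ", "), "]")
  }
  d <- dimv[2:4]
  datatype <- readBin(hdr[71:72], "integer", 1, size = 2, endian = "little")
  pixdim <- readBin(hdr[77:108], "double", 8, size = 4, endian = "little")
  vox_offset <- readBin(hdr[109:112], "double", 1, size = 4, endian = "little")
  scl_slope <- readBin(hdr[113:116], "double", 1, size = 4, endian = "little")
  scl_inter <- readBin(hdr[117:120], "double", 1, size = 4, endian = "little")
  n <- prod(d)
  skip <- max(0, vox_offset - 348)
  if (skip > 0) readBin(con, "raw", skip)
  vals <- switch(as.character(datatype),
    "2" = readBin(con, "integer", n, size = 1, signed = FALSE,
                  endian = "little"),
    "4" = readBin(con, "integer", n, size = 2, endian = "little"),
    "8" = readBin(con, "integer", n, size = 4, endian = "little"),
    "16" = readBin(con, "double", n, size = 4, endian = "little"),
    "64" = readBin(con, "double", n, size = 8, endian = "little"),
    stop("unsupported NIfTI datatype code ", datatype))
  if (length(vals) != n) stop("truncated NIfTI data in ", path)
  if (!all(is.finite(vals))) stop("non-finite voxels in ", path)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  out <- array(vals, d)
  attr(out, "spacing") <- pixdim[2:4]
  out
}

#' Read a NIfTI mask, validating that it is binary
#'
#' @param path .nii or .nii.gz file with values in \{0, 1\}.
#' @param volume_shape Optional shape to validate against.
#' @return Logical 3D array with attribute \code{spacing}.
#' @export
read_nifti_mask <- function(path, volume_shape = NULL) {
  v <- read_nifti(path)
  u <- unique(as.vector(v))
  if (!all(u %in% c(0, 1)))
    stop("mask ", path, " is not binary: values ",
         paste(utils::head(setdiff(u, c(0, 1)), 3), collapse = ", "))
  if (!is.null(volume_shape) && !all(dim(v) == volume_shape))
    stop("mask shape (", paste(dim(v), collapse = "x"),
         ") does not match volume shape (",
         paste(volume_shape, collapse = "x"), ")")
  out <- array(v != 0, dim(v))
  attr(out, "spacing") <- attr(v, "spacing")
  out
}
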