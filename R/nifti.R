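# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# Only the subset of the format this package produces and consumes is
# supported: 3D volumes, sform (or qform/pixdim fallback) affines, scalar
# integer or float datatypes, optional scl_slope/scl_inter scaling. No R
# package on the dependency stack provides NIfTI, so this is implemented on
# base readBin/writeBin; gzfile() transparently handles both compressed and
# uncompressed files.

nifti_dtype <- function(code) {
  switch(as.character(code),
    "2"   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
    "4"   = list(what = "integer", size = 2L, signed = TRUE),   # int16
    "8"   = list(what = "integer", size = 4L, signed = TRUE),   # int32
    "16"  = list(what = "double",  size = 4L, signed = TRUE),   # float32
    "64"  = list(what = "double",  size = 8L, signed = TRUE),   # float64
    "256" = list(what = "integer", size = 1L, signed = TRUE),   # int8
    "512" = list(what = "integer", size = 2L, signed = FALSE),  # uint16
    stop("nifti_unsupported_datatype: code ", code, call. = FALSE)
  )
}

#' Read a NIfTI-1 volume
#'
#' Internal low-level reader. Returns the voxel array, the voxel-to-mm affine
#' (0-based voxel indices on the input side, RAS-oriented mm on the output
#' side, as stored in the sform), and selected header fields.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return list with `data` (3D numeric array), `affine` (4x4 matrix),
#'   `pixdim` (length-3), `datatype` (NIfTI code).
#' @keywords internal
read_nifti <- function(path) {
  if (!file.exists(path)) {
    stop("nifti_file_missing: no such file: ", path, call. = FALSE)
  }
  con <- gzfile(path, "rb")
  on.exit(close(con))

  hdr_raw <- readBin(con, "raw", 348L)
  if (length(hdr_raw) < 348L) {
    stop("nifti_bad_header: file shorter than a NIfTI-1 header", call. = FALSE)
  }
  endian <- "little"
  if (readBin(hdr_raw[1:4], "integer", 1, size = 4, endian = endian) != 348L) {
    endian <- "big"
    if (readBin(hdr_raw[1:4], "integer", 1, size = 4, endian = endian) != 348L) {
      stop("nifti_bad_header: sizeof_hdr is not 348", call. = FALSE)
    }
  }
  at_i <- function(off, n, size) {
    readBin(hdr_raw[(off + 1):(off + n * size)], "integer", n,
            size = size, endian = endian)
  }
  at_f <- function(off, n) {
    readBin(hdr_raw[(off + 1):(off + n * 4)], "double", n,
            size = 4, endian = endian)
  }

  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) {
    stop("nifti_bad_header: bad magic '", magic, "'", call. = FALSE)
  }
  if (magic == "ni1") {
    stop("nifti_unsupported: two-file (.hdr/.img) NIfTI not supported",
         call. = FALSE)
  }

  dim_field <- at_i(40, 8, 2)
  ndim <- dim_field[1]
  if (ndim < 3L || any(dim_field[2:4] < 1L)) {
    stop("nifti_unsupported: need a 3D volume, got dim = ",
         paste(dim_field, collapse = " "), call. = FALSE)
  }
  if (ndim > 3L && any(dim_field[5:(1 + ndim)] > 1L)) {
    stop("nifti_unsupported: >3D volumes not supported", call. = FALSE)
  }
  dims <- dim_field[2:4]

  datatype <- at_i(70, 1, 2)
  dt <- nifti_dtype(datatype)
  pixdim <- at_f(76, 8)
  vox_offset <- at_f(108, 1)
  scl_slope <- at_f(112, 1)
  scl_inter <- at_f(116, 1)
  qform_code <- at_i(252, 1, 2)
  sform_code <- at_i(254, 1, 2)

  affine <- if (sform_code > 0L) {
    rbind(at_f(280, 4), at_f(296, 4), at_f(312, 4), c(0, 0, 0, 1))
  } else if (qform_code > 0L) {
    quatern_to_affine(b = at_f(256, 1), c = at_f(260, 1), d = at_f(264, 1),
                      qoffset = c(at_f(268, 1), at_f(272, 1), at_f(276, 1)),
                      pixdim = pixdim)
  } else {
    # method 1: scale by pixdim, arbitrary origin at 0
    diag(c(pixdim[2:4], 1))
  }

  # data start: skip any extension bytes between header end and vox_offset
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", skip)

  n_vox <- prod(dims)
  data <- readBin(con, dt$what, n_vox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(data) < n_vox) {
    stop("nifti_truncated: expected ", n_vox, " voxels, got ", length(data),
         call. = FALSE)
  }
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    data <- data * scl_slope + scl_inter
  }
  dim(data) <- dims
  list(data = data, affine = affine, pixdim = pixdim[2:4], datatype = datatype)
}

# qform method-2 affine from quaternion (a derived from unit norm)
quatern_to_affine <- function(b, c, d, qoffset, pixdim) {
  a2 <- 1 - b * b - c * c - d * d
  a <- if (a2 < 0) 0 else sqrt(a2)
  R <- matrix(c(
    a * a + b * b - c * c - d * d, 2 * (b * c - a * d),           2 * (b * d + a * c),
    2 * (b * c + a * d),           a * a + c * c - b * b - d * d, 2 * (c * d - a * b),
    2 * (b * d - a * c),           2 * (c * d + a * b),           a * a + d * d - b * b - c * c
  ), nrow = 3, byrow = TRUE)
  qfac <- if (pixdim[1] < 0) -1 else 1
  R <- R %*% diag(c(pixdim[2], pixdim[3], qfac * pixdim[4]))
  rbind(cbind(R, qoffset), c(0, 0, 0, 1))
}

#' Write a NIfTI-1 volume
#'
#' Internal low-level writer. Emits a single-file NIfTI-1 image with the
#' affine stored in both sform and (diagonal-compatible) pixdim. Integer data
#' are stored as int32, other data as float64.
#'
#' @param data 3D array.
#' @param affine 4x4 voxel-index (0-based) to mm map.
#' @param path output path; compressed iff it ends in `.gz`.
#' @keywords internal
write_nifti <- function(data, affine, path) {
  stopifnot(length(dim(data)) == 3L, all(dim(affine) == c(4L, 4L)))
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop("nifti_unwritable: directory does not exist: ", dir, call. = FALSE)
  }
  integral <- is.integer(data) ||
    (is.numeric(data) && all(data == round(data)))
  datatype <- if (integral) 8L else 64L
  bitpix <- if (integral) 32L else 64L

  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  w_f <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i(348L, 4)                              # sizeof_hdr
  w_raw(35)                                 # data_type, db_name, extents, session_error, regular
  w_raw(1)                                  # dim_info
  w_i(c(3L, dim(data), 1L, 1L, 1L, 1L), 2)  # dim[8]
  w_f(c(0, 0, 0))                           # intent_p1..3
  w_i(0L, 2)                                # intent_code
  w_i(datatype, 2)                          # datatype
  w_i(bitpix, 2)                            # bitpix
  w_i(0L, 2)                                # slice_start
  w_f(c(1, spacing, rep(0, 4)))             # pixdim[8], qfac = 1
  w_f(352)                                  # vox_offset
  w_f(1); w_f(0)                            # scl_slope, scl_inter
  w_i(0L, 2); w_raw(2)                      # slice_end, slice_code, xyzt_units
  w_f(c(0, 0, 0, 0))                        # cal_max, cal_min, slice_duration, toffset
  w_i(c(0L, 0L), 4)                         # glmax, glmin
  desc <- charToRaw("meniscus3d label volume")
  writeBin(c(desc, raw(80 - length(desc))), con)  # descrip[80]
  w_raw(24)                                 # aux_file
  w_i(0L, 2)                                # qform_code
  w_i(1L, 2)                                # sform_code (NIFTI_XFORM_SCANNER_ANAT)
  w_f(c(0, 0, 0, 0, 0, 0))                  # quatern b,c,d + qoffset x,y,z
  w_f(affine[1, ]); w_f(affine[2, ]); w_f(affine[3, ])  # srow_x/y/z
  w_raw(16)                                 # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  w_raw(4)                                  # pad to vox_offset = 352

  if (integral) {
    writeBin(as.integer(data), con, size = 4, endian = "little")
  } else {
    writeBin(as.numeric(data), con, size = 8, endian = "little")
  }
  invisible(path)
}
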