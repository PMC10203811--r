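# Minimal NIfTI-1 I/O.
#
# The pre-installed R stack has no NIfTI package, so the package carries a
# small single-file NIfTI-1 implementation: enough of the format (dim,
# pixdim, datatype, scl_slope/inter, sform) to exchange 3D/4D maps with
# standard neuroimaging tools. Little-endian on write; byte order detected
# on read via sizeof_hdr.

NIFTI_DTYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`  = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`  = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16` = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64` = list(what = "double",  size = 8L, signed = TRUE)    # float64
)

#' Build a voxel-to-mm affine for an axis-aligned RAS grid
#'
#' @param voxel_mm Voxel size in mm (scalar or length-3).
#' @param dim Spatial grid dimensions (length-3 integer).
#' @param centered If `TRUE` (default) the grid is centered on the origin
#'   (an MNI-like convention); otherwise voxel (1,1,1) sits at mm (0,0,0).
#' @return A 4x4 affine matrix mapping 1-based voxel indices to mm.
#' @export
ras_affine <- function(voxel_mm, dim, centered = TRUE) {
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3L)
  dim <- as.integer(dim[1:3])
  aff <- diag(c(voxel_mm, 1))
  if (centered) {
    aff[1:3, 4] <- -voxel_mm * (dim + 1) / 2
  } else {
    aff[1:3, 4] <- -voxel_mm
  }
  aff
}

#' Convert 1-based voxel indices to mm coordinates
#'
#' @param ijk Integer matrix (n x 3) or vector of 1-based voxel indices.
#' @param affine 4x4 voxel-to-mm affine.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_to_mm <- function(ijk, affine) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  t(affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
}

#' Write a 3D or 4D array as a NIfTI-1 file
#'
#' @param data Numeric 3D or 4D array.
#' @param path Output path; `.gz` suffix selects gzip compression.
#' @param affine 4x4 voxel-to-mm affine (sform, code 2).
#' @param tr Repetition time in seconds (written to pixdim[5] for 4D data).
#' @param datatype NIfTI datatype code; 16 = float32 (default), 64 = float64.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, affine = ras_affine(1, dim(data)),
                        tr = 1, datatype = 16L) {
  nd <- length(dim(data))
  stopifnot_msg(nd %in% c(3L, 4L), "data must be a 3D or 4D array")
  stopifnot_msg(as.character(datatype) %in% names(NIFTI_DTYPES),
                "unsupported NIfTI datatype code")
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  dims <- dim(data)
  dim8 <- c(nd, dims, rep(1L, 7L - length(dims)))
  voxdim <- sqrt(colSums(affine[1:3, 1:3]^2))
  pixdim <- c(1, voxdim, if (nd == 4L) tr else 1, 1, 1, 1)

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348L)                      # sizeof_hdr
  w_raw(36L)                       # data_type, db_name, extents, session_error, regular, dim_info
  w_i16(dim8)                      # dim[8]
  w_raw(14L)                       # intent_p1..3, intent_code
  w_i16(datatype)                  # datatype
  w_i16(8L * dt$size)              # bitpix
  w_i16(0L)                        # slice_start
  w_f32(pixdim)                    # pixdim[8]
  w_f32(352)                       # vox_offset
  w_f32(c(1, 0))                   # scl_slope, scl_inter
  w_i16(0L); w_raw(1L); w_raw(1L)  # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0))                # cal_max, cal_min, slice_duration
  w_f32(0)                         # toffset
  w_i32(c(0L, 0L))                 # glmax, glmin
  w_raw(80L); w_raw(24L)           # descrip, aux_file
  w_i16(0L)                        # qform_code
  w_i16(2L)                        # sform_code
  w_f32(rep(0, 6))                 # quatern b,c,d + qoffset x,y,z
  # srow uses 0-based voxel indices: shift the translation column
  srow <- affine
  srow[1:3, 4] <- affine[1:3, 4] + affine[1:3, 1:3] %*% rep(1, 3)
  w_f32(srow[1, ]); w_f32(srow[2, ]); w_f32(srow[3, ])
  w_raw(16L)                       # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con)  # magic, ends header at 348
  w_raw(4L)                        # extension flag -> offset 352

  if (dt$what == "integer") {
    writeBin(as.integer(round(data)), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.numeric(data), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 file
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with `data` (numeric array), `affine` (4x4, 1-based voxel
#'   to mm), `tr` (seconds; pixdim[5]) and `dim`.
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 352L)
  stopifnot_msg(length(hdr) == 352L, "file too short for a NIfTI-1 header")
  rd <- function(off, what, n, size) {
    readBin(hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian, signed = TRUE)
  }
  endian <- "little"
  if (readBin(hdr[1:4], "integer", size = 4L, endian = "little") != 348L)
    endian <- "big"
  stopifnot_msg(rd(0, "integer", 1, 4) == 348L, "not a NIfTI-1 file")

  dim8 <- rd(40, "integer", 8, 2)
  nd <- dim8[1]
  dims <- dim8[2:(1 + nd)]
  datatype <- rd(70, "integer", 1, 2)
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  stopifnot_msg(!is.null(dt), sprintf("unsupported NIfTI datatype %d", datatype))
  pixdim <- rd(76, "double", 8, 4)
  vox_offset <- rd(108, "double", 1, 4)
  scl_slope <- rd(112, "double", 1, 4)
  scl_inter <- rd(116, "double", 1, 4)
  sform_code <- rd(254, "integer", 1, 2)
  srow <- rbind(rd(280, "double", 4, 4), rd(296, "double", 4, 4),
                rd(312, "double", 4, 4), c(0, 0, 0, 1))

  skip <- vox_offset - 352
  if (skip > 0) readBin(con, "raw", n = skip)
  n_vox <- prod(dims)
  vals <- readBin(con, dt$what, n = n_vox, size = dt$size, endian = endian,
                  signed = dt$signed)
  stopifnot_msg(length(vals) == n_vox, "truncated NIfTI data section")
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter

  affine <- if (sform_code > 0) {
    a <- srow
    a[1:3, 4] <- srow[1:3, 4] - srow[1:3, 1:3] %*% rep(1, 3)
    a
  } else {
    ras_affine(pixdim[2:4], dims, centered = FALSE)
  }
  list(data = array(as.numeric(vals), dim = dims), affine = affine,
       tr = pixdim[5], dim = dims)
}
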