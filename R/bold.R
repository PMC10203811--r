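#' Construct a 4D BOLD series
#'
#' Container for a 4D fMRI acquisition: the intensity grid, repetition time,
#' voxel-to-mm affine, and a 3D brain mask.
#'
#' @param data Numeric 4D array (x, y, z, t), arbitrary scanner units.
#' @param tr Repetition time in seconds.
#' @param affine 4x4 voxel-to-mm affine; default axis-aligned from `voxel_mm`.
#' @param mask Logical 3D array matching the spatial grid; default all-TRUE.
#' @param voxel_mm Voxel size used for the default affine.
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(data, tr, affine = NULL, mask = NULL, voxel_mm = 3) {
  stopifnot_msg(is.array(data) && length(dim(data)) == 4L,
                "data must be a 4D array (x, y, z, t)")
  stopifnot_msg(dim(data)[4] >= 2L, "need at least 2 time points")
  stopifnot_msg(is.numeric(tr) && tr > 0, "tr must be > 0 seconds")
  sdim <- dim(data)[1:3]
  if (is.null(affine)) affine <- ras_affine(voxel_mm, sdim)
  if (is.null(mask)) mask <- array(TRUE, sdim)
  stopifnot_msg(identical(dim(mask), sdim),
                "mask shape must equal the spatial shape of data")
  structure(list(data = data, tr = tr, affine = affine,
                 mask = array(as.logical(mask), sdim)),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_series> %dx%dx%d voxels, %d volumes, TR = %g s, %d voxels in mask\n",
              d[1], d[2], d[3], d[4], x$tr, sum(x$mask)))
  invisible(x)
}

#' Construct an amplitude map (PerAF or mPerAF)
#'
#' @param data Numeric 3D array of amplitude values. PerAF is in percent
#'   units and non-negative; mPerAF is a unitless ratio with mean 1 over its
#'   normalization mask.
#' @param kind Either `"peraf"` or `"mperaf"`.
#' @param mask Logical 3D array of valid voxels.
#' @param affine 4x4 voxel-to-mm affine.
#' @param band Band edges in Hz used upstream (provenance).
#' @param norm_mask Normalization mask (mPerAF only; provenance).
#' @param qc Data frame of flagged voxels (zero/negative mean or zero
#'   variance), one row per flagged voxel.
#' @return An object of class `amplitude_map`.
#' @export
amplitude_map <- function(data, kind = c("peraf", "mperaf"), mask,
                          affine = ras_affine(3, dim(data)),
                          band = c(NA_real_, NA_real_), norm_mask = NULL,
                          qc = NULL) {
  kind <- match.arg(kind)
  stopifnot_msg(is.array(data) && length(dim(data)) == 3L, "data must be 3D")
  if (kind == "peraf")
    stopifnot_msg(all(data[mask] >= 0), "PerAF values must be non-negative")
  structure(list(data = data, kind = kind, mask = mask, affine = affine,
                 band = band, norm_mask = norm_mask, qc = qc),
            class = "amplitude_map")
}

#' @export
print.amplitude_map <- function(x, ...) {
  cat(sprintf("<amplitude_map> kind = %s, %d voxels in mask, band = [%g, %g] Hz\n",
              x$kind, sum(x$mask), x$band[1], x$band[2]))
  invisible(x)
}
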