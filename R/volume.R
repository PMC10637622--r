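#' Geometric volume: voxels plus a voxel-to-world affine
#'
#' The in-memory equivalent of a single-file NIfTI volume. Voxels are indexed
#' \code{[i_col, i_row, i_slice]} (zero-based in affine arithmetic): the first
#' index runs along a displayed image row, the second down the image, the
#' third across slices. The affine maps zero-based voxel indices to world
#' millimetres in RAS orientation (NIfTI convention; DICOM positions are LPS
#' and are converted by negating x and y).
#'
#' @param voxels 3-D numeric/integer array.
#' @param affine 4x4 matrix, voxel index (0-based, homogeneous) to RAS mm.
#' @param source_sop_uids SOP instance UIDs of the source slices, aligned with
#'   the slice axis; empty for synthetic masks.
#' @param study_uid,series_uid UIDs of the originating study/series, if any.
#' @return A \code{geometric_volume}.
#' @export
geometric_volume <- function(voxels, affine, source_sop_uids = character(0),
                             study_uid = NULL, series_uid = NULL) {
  if (length(dim(voxels)) != 3L)
    qv_stop("qv_validation_error", "voxels must be a 3-D array")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    qv_stop("qv_validation_error", "affine must be 4x4")
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    qv_stop("qv_geometry_error", "affine upper-left 3x3 is singular")
  if (length(source_sop_uids) > 0L &&
      length(source_sop_uids) != dim(voxels)[3L])
    qv_stop("qv_validation_error",
            "source_sop_uids length must equal the slice-axis extent")
  structure(list(voxels = voxels, affine = affine,
                 source_sop_uids = source_sop_uids,
                 study_uid = study_uid, series_uid = series_uid),
            class = "geometric_volume")
}

#' @export
print.geometric_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<geometric_volume %d x %d x %d>\n", d[1], d[2], d[3]))
  cat(sprintf("  voxel volume: %.6g mm^3\n", abs(det(x$affine[1:3, 1:3]))))
  cat(sprintf("  value range: [%.4g, %.4g]\n",
              min(x$voxels), max(x$voxels)))
  if (length(x$source_sop_uids))
    cat(sprintf("  source slices: %d\n", length(x$source_sop_uids)))
  invisible(x)
}

#' Map voxel indices to world coordinates
#' @param v a \code{geometric_volume}.
#' @param idx n x 3 matrix of zero-based voxel indices.
#' @return n x 3 matrix of RAS world coordinates in mm.
#' @export
voxel_to_world <- function(v, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3L)
  h <- cbind(idx, 1)
  t(v$affine %*% t(h))[, 1:3, drop = FALSE]
}
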