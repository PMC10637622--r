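# DICOM stack -> geometric volume (the DICOM-to-NIfTI step), and single-file
# NIfTI read/write.

#' Sort a DICOM slice stack along the slice normal
#'
#' Orders instances by ascending projection of ImagePositionPatient onto the
#' slice normal (cross product of the row and column direction cosines) and
#' measures the slice step as the mean adjacent projection difference.
#' Sorting never uses InstanceNumber, which is vendor-dependent.
#'
#' @param instances list of \code{dicom_dataset} slices from one series.
#' @return list with \code{instances} (ordered) and \code{slice_step_mm}.
#'   For a single slice the step falls back to the SliceThickness tag.
#' @export
sort_slices <- function(instances) {
  if (length(instances) < 1L)
    qv_stop("qv_geometry_error", "no instances to sort")
  series <- vapply(instances, dcm_get, character(1), name = "SeriesInstanceUID")
  if (length(unique(series)) != 1L)
    qv_stop("qv_geometry_error", "instances span multiple series")
  iops <- t(vapply(instances, dcm_get, numeric(6),
                   name = "ImageOrientationPatient"))
  if (any(abs(sweep(iops, 2L, iops[1L, ])) > 1e-4))
    qv_stop("qv_geometry_error", "mixed image orientation within series")
  pss <- t(vapply(instances, dcm_get, numeric(2), name = "PixelSpacing"))
  if (any(abs(sweep(pss, 2L, pss[1L, ])) > 1e-6))
    qv_stop("qv_geometry_error", "mixed pixel spacing within series")
  dims <- t(vapply(instances, function(x)
    c(dcm_get(x, "Rows"), dcm_get(x, "Columns")), numeric(2)))
  if (any(dims[, 1L] != dims[1L, 1L]) || any(dims[, 2L] != dims[1L, 2L]))
    qv_stop("qv_geometry_error", "mixed matrix size within series")

  normal <- qv_slice_normal(iops[1L, ])
  proj <- vapply(instances, function(x)
    sum(dcm_get(x, "ImagePositionPatient") * normal), numeric(1))
  ord <- order(proj)
  proj <- proj[ord]
  instances <- instances[ord]

  if (length(instances) == 1L) {
    step <- dcm_get(instances[[1L]], "SliceThickness")
    if (is.null(step))
      qv_stop("qv_geometry_error",
              "single slice without SliceThickness: slice step unknown")
    return(list(instances = instances, slice_step_mm = as.numeric(step)))
  }
  d <- diff(proj)
  if (any(d <= 0) || anyDuplicated(proj))
    qv_stop("qv_geometry_error", "duplicate slice positions along the normal")
  step <- mean(d)
  if (any(abs(d - step) > 0.01 * abs(step)))
    qv_stop("qv_geometry_error",
            sprintf("non-uniform slice spacing (steps %s vs mean %.4g)",
                    paste(sprintf("%.4g", range(d)), collapse = ".."), step))
  list(instances = instances, slice_step_mm = step)
}

#' Assemble a DICOM slice stack into a geometric volume
#'
#' Voxels are indexed \code{[i_col, i_row, i_slice]} and hold rescaled HU.
#' The affine maps zero-based voxel indices to RAS world mm: DICOM LPS
#' positions and direction cosines are converted by negating x and y.
#'
#' @param instances list of \code{dicom_dataset} slices from one series (any
#'   order; assembly is permutation-invariant).
#' @return A \code{geometric_volume} with \code{source_sop_uids} in sorted
#'   slice order.
#' @export
assemble_volume <- function(instances) {
  s <- sort_slices(instances)
  instances <- s$instances
  first <- instances[[1L]]
  rows <- as.integer(dcm_get(first, "Rows"))
  cols <- as.integer(dcm_get(first, "Columns"))
  n <- length(instances)
  ps <- dcm_get(first, "PixelSpacing")          # (row, col) spacing
  iop <- dcm_get(first, "ImageOrientationPatient")
  r_dir <- iop[1:3]; c_dir <- iop[4:6]
  n_dir <- qv_slice_normal(iop)
  origin <- dcm_get(first, "ImagePositionPatient")

  vox <- array(0, c(cols, rows, n))
  for (i in seq_len(n)) vox[, , i] <- dcm_hu_matrix(instances[[i]])

  a_lps <- cbind(c(r_dir * ps[2L], 0), c(c_dir * ps[1L], 0),
                 c(n_dir * s$slice_step_mm, 0), c(origin, 1))
  affine <- diag(c(-1, -1, 1, 1)) %*% a_lps
  geometric_volume(
    vox, affine,
    source_sop_uids = vapply(instances, dcm_get, character(1),
                             name = "SOPInstanceUID"),
    study_uid = dcm_get(first, "StudyInstanceUID"),
    series_uid = dcm_get(first, "SeriesInstanceUID"))
}

#' Write a geometric volume as single-file NIfTI-1
#'
#' Integer-valued volumes within 16-bit range are stored as int16, everything
#' else as 32-bit float; the affine is stored in the sform (code 2).
#'
#' @param v a \code{geometric_volume}.
#' @param path output path, conventionally ending in ".nii.gz".
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "geometric_volume"))
  vox <- v$voxels
  int_valued <- all(vox == round(vox)) && min(vox) >= -32768 && max(vox) <= 32767
  img <- RNifti::asNifti(vox)
  img <- RNifti::`sform<-`(img, value = structure(v$affine, code = 2L))
  RNifti::writeNifti(img, path,
                     datatype = if (int_valued) "int16" else "float")
  invisible(path)
}

#' Read a single-file NIfTI-1 volume
#'
#' @param path path to a .nii / .nii.gz file.
#' @return A \code{geometric_volume} (with empty \code{source_sop_uids}; the
#'   NIfTI format does not carry the DICOM UID tree).
#' @export
read_volume <- function(path) {
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e)
                    qv_stop("qv_format_error",
                            sprintf("cannot read NIfTI file %s: %s",
                                    path, conditionMessage(e))))
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  attributes(aff) <- list(dim = dim(aff))
  vox <- array(as.vector(img), dim(img)[1:3])
  geometric_volume(vox, rbind(aff[1:3, ], c(0, 0, 0, 1)))
}
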