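#' Synthetic CT phantom with ellipsoidal lesions
#'
#' Generates multi-slice axial CT series in which every lesion is an
#' ellipsoid of known analytic volume, together with the matching
#' ground-truth label volume on the identical grid. This makes the whole
#' routing / conversion / segmentation / encoding / volumetry chain testable
#' without any external dataset. Defaults mirror a portal-venous abdominal
#' acquisition archived at 3 mm section thickness with on the order of
#' 91-203 slices per series.
#'
#' @param rows,cols image matrix size (default 64 x 64, a downsampled CT
#'   matrix that keeps test volumes small).
#' @param n_slices number of slices (default 120).
#' @param pixel_spacing_mm length-2 numeric, (row, column) spacing in mm.
#' @param slice_thickness_mm section thickness in mm (default 3).
#' @param slice_spacing_mm distance between adjacent slice positions;
#'   defaults to \code{slice_thickness_mm} (contiguous slices).
#' @param orientation direction-cosine 6-vector (row cosines then column
#'   cosines, LPS); default axial identity.
#' @param origin_mm position of the first slice's first pixel (LPS, mm).
#' @param background_hu Hounsfield value outside every lesion.
#' @param lesions list of \code{\link{ellipsoid_lesion}}.
#' @param patient_name,study_description,series_description demographic /
#'   descriptive tag values. The default series description contains
#'   "Portal Venous" so phantom series pass the shipped series filter.
#' @param seed integer seed for the UID random material.
#' @return A validated \code{phantom_spec}.
#' @export
phantom_spec <- function(rows = 64L, cols = 64L, n_slices = 120L,
                         pixel_spacing_mm = c(0.8, 0.8),
                         slice_thickness_mm = 3.0,
                         slice_spacing_mm = slice_thickness_mm,
                         orientation = c(1, 0, 0, 0, 1, 0),
                         origin_mm = c(-100, -80, 50),
                         background_hu = 0,
                         lesions = list(),
                         patient_name = "PHANTOM^QV",
                         study_description = "QV PHANTOM STUDY",
                         series_description = "ABD PEL Portal Venous 3.0mm",
                         seed = 1L) {
  spec <- structure(list(
    rows = as.integer(rows), cols = as.integer(cols),
    n_slices = as.integer(n_slices),
    pixel_spacing_mm = as.numeric(pixel_spacing_mm),
    slice_thickness_mm = as.numeric(slice_thickness_mm),
    slice_spacing_mm = as.numeric(slice_spacing_mm),
    orientation = as.numeric(orientation),
    origin_mm = as.numeric(origin_mm),
    background_hu = as.numeric(background_hu),
    lesions = lesions,
    patient_name = patient_name,
    study_description = study_description,
    series_description = series_description,
    seed = as.integer(seed)), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' Ellipsoidal lesion description
#'
#' @param center_mm ellipsoid centre in patient (LPS) mm.
#' @param radii_mm three positive semi-axis lengths in mm.
#' @param hu Hounsfield value of the lesion interior.
#' @param label_value positive integer label in the ground-truth mask;
#'   must be unique within a spec.
#' @return An \code{ellipsoid_lesion}.
#' @export
ellipsoid_lesion <- function(center_mm, radii_mm, hu = 60, label_value = 1L) {
  l <- structure(list(center_mm = as.numeric(center_mm),
                      radii_mm = as.numeric(radii_mm),
                      hu = as.numeric(hu),
                      label_value = as.integer(label_value)),
                 class = "ellipsoid_lesion")
  if (length(l$radii_mm) != 3L || any(!is.finite(l$radii_mm)) ||
      any(l$radii_mm <= 0))
    qv_stop("qv_validation_error", "lesion radii_mm must be 3 positive reals",
            field = "radii_mm")
  if (length(l$center_mm) != 3L || any(!is.finite(l$center_mm)))
    qv_stop("qv_validation_error", "lesion center_mm must be a 3-vector",
            field = "center_mm")
  if (l$label_value < 1L)
    qv_stop("qv_validation_error", "label_value must be a positive integer",
            field = "label_value")
  l
}

validate_phantom_spec <- function(spec) {
  if (spec$n_slices < 1L)
    qv_stop("qv_validation_error", "n_slices must be >= 1", field = "n_slices")
  if (spec$rows < 1L || spec$cols < 1L)
    qv_stop("qv_validation_error", "rows/cols must be >= 1", field = "rows")
  if (length(spec$pixel_spacing_mm) != 2L || any(spec$pixel_spacing_mm <= 0))
    qv_stop("qv_validation_error", "pixel_spacing_mm must be 2 positive reals",
            field = "pixel_spacing_mm")
  if (spec$slice_thickness_mm <= 0)
    qv_stop("qv_validation_error", "slice_thickness_mm must be positive",
            field = "slice_thickness_mm")
  if (spec$slice_spacing_mm <= 0)
    qv_stop("qv_validation_error", "slice_spacing_mm must be positive",
            field = "slice_spacing_mm")
  o <- spec$orientation
  if (length(o) != 6L)
    qv_stop("qv_validation_error", "orientation must be a 6-vector",
            field = "orientation")
  r <- o[1:3]; c_ <- o[4:6]
  if (abs(sqrt(sum(r^2)) - 1) > 1e-6 || abs(sqrt(sum(c_^2)) - 1) > 1e-6 ||
      abs(sum(r * c_)) > 1e-6)
    qv_stop("qv_validation_error",
            "orientation cosines must be unit-length and orthogonal",
            field = "orientation")
  labs <- vapply(spec$lesions, function(l) l$label_value, integer(1))
  if (anyDuplicated(labs))
    qv_stop("qv_validation_error", "lesion label_value must be unique",
            field = "lesions")
  invisible(TRUE)
}

# slice normal: cross product of row and column cosines
qv_slice_normal <- function(orientation) {
  r <- orientation[1:3]; c_ <- orientation[4:6]
  c(r[2] * c_[3] - r[3] * c_[2],
    r[3] * c_[1] - r[1] * c_[3],
    r[1] * c_[2] - r[2] * c_[1])
}

#' Voxel grid of a phantom spec
#'
#' @param spec a \code{phantom_spec}.
#' @return list with \code{dims} (cols, rows, n_slices), the RAS \code{affine},
#'   and \code{lps_coords()} — a function returning the LPS world coordinates
#'   of all voxel centers as three arrays X, Y, Z.
#' @keywords internal
phantom_grid <- function(spec) {
  r_dir <- spec$orientation[1:3]
  c_dir <- spec$orientation[4:6]
  n_dir <- qv_slice_normal(spec$orientation)
  ps_row <- spec$pixel_spacing_mm[1]   # spacing between rows (along c_dir)
  ps_col <- spec$pixel_spacing_mm[2]   # spacing between columns (along r_dir)
  step <- spec$slice_spacing_mm
  origin <- spec$origin_mm
  a_lps <- cbind(c(r_dir * ps_col, 0), c(c_dir * ps_row, 0),
                 c(n_dir * step, 0), c(origin, 1))
  flip <- diag(c(-1, -1, 1, 1))
  list(
    dims = c(spec$cols, spec$rows, spec$n_slices),
    affine = flip %*% a_lps,
    r_dir = r_dir, c_dir = c_dir, n_dir = n_dir,
    ps_row = ps_row, ps_col = ps_col, step = step, origin = origin
  )
}

# LPS coordinates of every voxel center, as three arrays of dim (cols, rows, n_slices)
qv_grid_coords_lps <- function(spec) {
  g <- phantom_grid(spec)
  ci <- seq_len(spec$cols) - 1
  ri <- seq_len(spec$rows) - 1
  si <- seq_len(spec$n_slices) - 1
  d <- g$dims
  coord <- function(ax) {
    a <- g$origin[ax] +
      outer(ci * g$ps_col * g$r_dir[ax],
            ri * g$ps_row * g$c_dir[ax], "+")
    outer(a, si * g$step * g$n_dir[ax], "+")
  }
  list(x = array(coord(1), d), y = array(coord(2), d), z = array(coord(3), d))
}

#' Ground-truth label volume of a phantom
#'
#' Rasterizes each lesion by voxel-center inclusion: a voxel gets the lesion's
#' label when its center satisfies the normalized ellipsoid inequality
#' \eqn{\sum ((x_i - c_i)/r_i)^2 \le 1} (surface included). Later lesions in
#' the list overwrite earlier ones where they overlap.
#'
#' @param spec a \code{phantom_spec}.
#' @return A \code{geometric_volume} of integer labels on the identical grid
#'   as \code{\link{generate_ct_series}}.
#' @export
ground_truth_mask <- function(spec) {
  validate_phantom_spec(spec)
  g <- phantom_grid(spec)
  mask <- array(0L, g$dims)
  if (length(spec$lesions)) {
    co <- qv_grid_coords_lps(spec)
    for (l in spec$lesions) {
      d2 <- ((co$x - l$center_mm[1]) / l$radii_mm[1])^2 +
            ((co$y - l$center_mm[2]) / l$radii_mm[2])^2 +
            ((co$z - l$center_mm[3]) / l$radii_mm[3])^2
      mask[d2 <= 1] <- l$label_value
    }
  }
  geometric_volume(mask, g$affine)
}

#' Analytic ellipsoid volume in milliliters
#' @param lesion an \code{ellipsoid_lesion}.
#' @return \eqn{(4/3)\pi r_1 r_2 r_3 / 1000} in mL.
#' @export
analytic_volume_ml <- function(lesion) {
  r <- lesion$radii_mm
  if (any(r <= 0))
    qv_stop("qv_validation_error", "radii must be positive", field = "radii_mm")
  (4 / 3) * pi * prod(r) / 1000
}

#' Generate a synthetic CT series as DICOM instances
#'
#' Produces one instance per slice, all sharing a freshly minted study,
#' series, and frame-of-reference UID, with HU pixel data encoded as signed
#' 16-bit stored values under RescaleSlope 1 / RescaleIntercept -1024. Pixel
#' content is analytic (no noise), so it is byte-identical across calls for a
#' fixed spec; UIDs are unique per call. The instances deliberately carry
#' identifying tags (patient name, accession number, institution, physician
#' and operator names, device serial, one private tag) so the anonymizer has
#' real work to do.
#'
#' @param spec a \code{phantom_spec}.
#' @return List of \code{dicom_dataset}, one per slice, in slice order.
#' @export
generate_ct_series <- function(spec) {
  validate_phantom_spec(spec)
  g <- phantom_grid(spec)

  hu <- array(spec$background_hu, g$dims)
  if (length(spec$lesions)) {
    co <- qv_grid_coords_lps(spec)
    for (l in spec$lesions) {
      d2 <- ((co$x - l$center_mm[1]) / l$radii_mm[1])^2 +
            ((co$y - l$center_mm[2]) / l$radii_mm[2])^2 +
            ((co$z - l$center_mm[3]) / l$radii_mm[3])^2
      hu[d2 <= 1] <- l$hu
    }
  }
  intercept <- -1024; slope <- 1
  stored <- (hu - intercept) / slope

  # UID random material is seeded from the spec for reproducibility; the
  # session RNG state is restored afterwards
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(spec$seed)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  study_uid <- new_uid()
  series_uid <- new_uid()
  frame_uid <- new_uid()
  sop_uids <- vapply(seq_len(spec$n_slices), function(i) new_uid(), character(1))

  lapply(seq_len(spec$n_slices), function(i) {
    pos <- g$origin + (i - 1) * g$step * g$n_dir
    ds <- dcm_dataset()
    ds <- dcm_set(ds, "SpecificCharacterSet", "ISO_IR 100")
    ds <- dcm_set(ds, "SOPClassUID", "1.2.840.10008.5.1.4.1.1.2")
    ds <- dcm_set(ds, "SOPInstanceUID", sop_uids[i])
    ds <- dcm_set(ds, "StudyInstanceUID", study_uid)
    ds <- dcm_set(ds, "SeriesInstanceUID", series_uid)
    ds <- dcm_set(ds, "FrameOfReferenceUID", frame_uid)
    ds <- dcm_set(ds, "Modality", "CT")
    ds <- dcm_set(ds, "ImageType", c("ORIGINAL", "PRIMARY", "AXIAL"))
    ds <- dcm_set(ds, "StudyDate", "20230101")
    ds <- dcm_set(ds, "StudyTime", "120000")
    ds <- dcm_set(ds, "StudyDescription", spec$study_description)
    ds <- dcm_set(ds, "SeriesDescription", spec$series_description)
    ds <- dcm_set(ds, "StudyID", "1")
    ds <- dcm_set(ds, "SeriesNumber", 1L)
    ds <- dcm_set(ds, "InstanceNumber", i)
    ds <- dcm_set(ds, "Manufacturer", "qvbridge phantom")
    ds <- dcm_set(ds, "PatientName", spec$patient_name)
    ds <- dcm_set(ds, "PatientID", "QV-PHANTOM-001")
    ds <- dcm_set(ds, "PatientBirthDate", "19700101")
    ds <- dcm_set(ds, "PatientSex", "O")
    ds <- dcm_set(ds, "AccessionNumber", "ACC0001")
    ds <- dcm_set(ds, "InstitutionName", "Phantom General Hospital")
    ds <- dcm_set(ds, "ReferringPhysicianName", "REFERRER^DR")
    ds <- dcm_set(ds, "OperatorsName", "TECH^ONE")
    ds <- dcm_set(ds, "DeviceSerialNumber", "SN-000123")
    ds <- dcm_set(ds, "PatientAddress", "1 Phantom Way")
    ds <- dcm_set_tag(ds, 0x0009, 0x0010, "LO", "PRIVATE CREATOR DATA")
    ds <- dcm_set(ds, "ImagePositionPatient", pos)
    ds <- dcm_set(ds, "ImageOrientationPatient", spec$orientation)
    ds <- dcm_set(ds, "PixelSpacing", spec$pixel_spacing_mm)
    ds <- dcm_set(ds, "SliceThickness", spec$slice_thickness_mm)
    ds <- dcm_set(ds, "SpacingBetweenSlices", spec$slice_spacing_mm)
    ds <- dcm_set(ds, "RescaleIntercept", intercept)
    ds <- dcm_set(ds, "RescaleSlope", slope)
    ds <- dcm_set(ds, "RescaleType", "HU")
    ds <- dcm_set(ds, "Rows", spec$rows)
    ds <- dcm_set(ds, "Columns", spec$cols)
    ds <- dcm_set(ds, "BitsAllocated", 16L)
    ds <- dcm_set(ds, "BitsStored", 16L)
    ds <- dcm_set(ds, "HighBit", 15L)
    ds <- dcm_set(ds, "PixelRepresentation", 1L)
    ds <- dcm_set(ds, "SamplesPerPixel", 1L)
    ds <- dcm_set(ds, "PhotometricInterpretation", "MONOCHROME2")
    ds <- dcm_set(ds, "PixelData", qv_encode_pixels16(stored[, , i]))
    ds
  })
}

#' Write a phantom series to part-10 files
#' @param instances output of \code{\link{generate_ct_series}}.
#' @param dir output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_series <- function(instances, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(instances, function(inst) {
    p <- file.path(dir, paste0(dcm_get(inst, "SOPInstanceUID"), ".dcm"))
    write_dicom(inst, p)
    p
  }, character(1))
  invisible(paths)
}
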