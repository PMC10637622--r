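#' Volumetry and structured-report generation
#'
#' The segmented volume in milliliters is computed along two independent
#' paths: directly from the DICOM SEG bit-packed pixel data (set-bit count
#' times the in-plane pixel area times the measured slice step), and from a
#' label volume (nonzero-voxel count times the affine's voxel volume). Both
#' count the same voxels, so they agree exactly; the cross-check mirrors
#' verifying SEG-derived volumes against NIfTI-derived ones. The result is
#' packaged as a DICOM Comprehensive SR with a numeric volume content item.
#'
#' @name qv-volumetry
NULL

.QV_SR_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.88.33"

#' Volume in mL from SEG pixel data
#'
#' Counts the set bits across all frames of the SEG object and multiplies by
#' the voxel volume: row spacing x column spacing x measured slice step
#' (from sorted source positions, not the SliceThickness tag, so gapped
#' acquisitions are measured correctly).
#'
#' @param seg a SEG \code{dicom_dataset}.
#' @param source list of source CT \code{dicom_dataset}s.
#' @return Volume in milliliters.
#' @export
seg_volume_ml <- function(seg, source) {
  validate_seg_linkage(seg, source)
  g <- qv_stack_geometry(source)
  nbits <- sum(seg_unpack_bits(seg))
  nbits * g$ps[1L] * g$ps[2L] * g$step / 1000
}

#' Volume in mL from a label volume
#'
#' @param mask integer label \code{geometric_volume}; every nonzero voxel
#'   counts.
#' @return Volume in milliliters: nonzero count x |det(affine 3x3)| / 1000.
#' @export
nifti_volume_ml <- function(mask) {
  stopifnot(inherits(mask, "geometric_volume"))
  d <- det(mask$affine[1:3, 1:3])
  if (abs(d) < 1e-12)
    qv_stop("qv_geometry_error", "singular affine")
  sum(mask$voxels != 0) * abs(d) / 1000
}

#' Render a volume statement
#'
#' Formats "<label> volume: <v> mL" with the value rounded to one decimal
#' and rendered without a trailing ".0" when integral.
#'
#' @param label segment label text.
#' @param volume_ml volume in mL.
#' @return character scalar.
#' @export
format_volume_statement <- function(label, volume_ml) {
  v1 <- round(volume_ml, 1L)
  vtxt <- if (abs(v1 - round(v1)) < 1e-9) sprintf("%d", as.integer(round(v1)))
          else sprintf("%.1f", v1)
  sprintf("%s volume: %s mL", label, vtxt)
}

#' Build the DICOM SR measurement report
#'
#' Produces a Comprehensive SR dataset containing a container with (i) a
#' numeric measurement content item (concept "Volume", UCUM milliliters,
#' value at full precision) and (ii) a text statement item; plus evidence
#' references tying the report to the source study/series and the SEG
#' object.
#'
#' @param volume_ml measured volume (>= 0) in mL.
#' @param desc a \code{segment_descriptor} (provides the label).
#' @param study_uid source study UID (inherited by the SR).
#' @param series_uid source series UID referenced as evidence.
#' @param seg_sop_uid,seg_series_uid SOP/series UIDs of the SEG object;
#'   may be NULL when no SEG exists (empty segmentation policy).
#' @param uid_root root for minted UIDs.
#' @return A \code{measurement_report}: list with \code{volume_ml},
#'   \code{label}, \code{statement}, the UID references, and \code{dataset}
#'   (the SR \code{dicom_dataset}).
#' @export
build_sr <- function(volume_ml, desc, study_uid, series_uid,
                     seg_sop_uid = NULL, seg_series_uid = NULL,
                     uid_root = qv_default_uid_root()) {
  if (!is.numeric(volume_ml) || length(volume_ml) != 1L || volume_ml < 0)
    qv_stop("qv_validation_error", "volume_ml must be a non-negative number",
            field = "volume_ml")
  statement <- format_volume_statement(desc$label, volume_ml)

  concept_volume <- dcm_dataset()
  concept_volume <- dcm_set(concept_volume, "CodeValue", "118565006")
  concept_volume <- dcm_set(concept_volume, "CodingSchemeDesignator", "SCT")
  concept_volume <- dcm_set(concept_volume, "CodeMeaning", "Volume")
  units_ml <- dcm_dataset()
  units_ml <- dcm_set(units_ml, "CodeValue", "ml")
  units_ml <- dcm_set(units_ml, "CodingSchemeDesignator", "UCUM")
  units_ml <- dcm_set(units_ml, "CodeMeaning", "milliliter")

  measured <- dcm_dataset()
  measured <- dcm_set(measured, "NumericValue", volume_ml)
  measured <- dcm_set(measured, "MeasurementUnitsCodeSequence",
                      list(units_ml))
  num_item <- dcm_dataset()
  num_item <- dcm_set(num_item, "RelationshipType", "CONTAINS")
  num_item <- dcm_set(num_item, "ValueType", "NUM")
  num_item <- dcm_set(num_item, "ConceptNameCodeSequence",
                      list(concept_volume))
  num_item <- dcm_set(num_item, "MeasuredValueSequence", list(measured))

  concept_finding <- dcm_dataset()
  concept_finding <- dcm_set(concept_finding, "CodeValue", "121071")
  concept_finding <- dcm_set(concept_finding, "CodingSchemeDesignator", "DCM")
  concept_finding <- dcm_set(concept_finding, "CodeMeaning", "Finding")
  text_item <- dcm_dataset()
  text_item <- dcm_set(text_item, "RelationshipType", "CONTAINS")
  text_item <- dcm_set(text_item, "ValueType", "TEXT")
  text_item <- dcm_set(text_item, "ConceptNameCodeSequence",
                       list(concept_finding))
  text_item <- dcm_set(text_item, "TextValue", statement)

  ref_series <- dcm_dataset()
  ref_series <- dcm_set(ref_series, "SeriesInstanceUID", series_uid)
  seg_refs <- list()
  if (!is.null(seg_sop_uid)) {
    ref_sop <- dcm_dataset()
    ref_sop <- dcm_set(ref_sop, "ReferencedSOPClassUID", .QV_SEG_SOP_CLASS)
    ref_sop <- dcm_set(ref_sop, "ReferencedSOPInstanceUID", seg_sop_uid)
    seg_series <- dcm_dataset()
    seg_series <- dcm_set(seg_series, "SeriesInstanceUID", seg_series_uid)
    seg_series <- dcm_set(seg_series, "ReferencedInstanceSequence",
                          list(ref_sop))
    seg_refs <- list(seg_series)
  }
  evidence <- dcm_dataset()
  evidence <- dcm_set(evidence, "StudyInstanceUID", study_uid)
  evidence <- dcm_set(evidence, "ReferencedSeriesSequence",
                      c(list(ref_series), seg_refs))

  concept_report <- dcm_dataset()
  concept_report <- dcm_set(concept_report, "CodeValue", "126000")
  concept_report <- dcm_set(concept_report, "CodingSchemeDesignator", "DCM")
  concept_report <- dcm_set(concept_report, "CodeMeaning",
                            "Imaging Measurement Report")

  ds <- dcm_dataset()
  ds <- dcm_set(ds, "SOPClassUID", .QV_SR_SOP_CLASS)
  ds <- dcm_set(ds, "SOPInstanceUID", new_uid(uid_root))
  ds <- dcm_set(ds, "StudyInstanceUID", study_uid)
  ds <- dcm_set(ds, "SeriesInstanceUID", new_uid(uid_root))
  ds <- dcm_set(ds, "Modality", "SR")
  ds <- dcm_set(ds, "SeriesDescription", "Volumetry report")
  ds <- dcm_set(ds, "SeriesNumber", 400L)
  ds <- dcm_set(ds, "InstanceNumber", 1L)
  ds <- dcm_set(ds, "ContentDate", format(Sys.Date(), "%Y%m%d"))
  ds <- dcm_set(ds, "ContentTime", format(Sys.time(), "%H%M%S"))
  ds <- dcm_set(ds, "CompletionFlag", "COMPLETE")
  ds <- dcm_set(ds, "VerificationFlag", "UNVERIFIED")
  ds <- dcm_set(ds, "ValueType", "CONTAINER")
  ds <- dcm_set(ds, "ConceptNameCodeSequence", list(concept_report))
  ds <- dcm_set(ds, "ContinuityOfContent", "SEPARATE")
  ds <- dcm_set(ds, "ContentSequence", list(num_item, text_item))
  ds <- dcm_set(ds, "CurrentRequestedProcedureEvidenceSequence",
                list(evidence))

  structure(list(volume_ml = volume_ml, label = desc$label,
                 statement = statement, study_uid = study_uid,
                 series_uid = series_uid, seg_sop_uid = seg_sop_uid,
                 seg_series_uid = seg_series_uid,
                 sop_instance_uid = dcm_get(ds, "SOPInstanceUID"),
                 dataset = ds),
            class = "measurement_report")
}

#' @export
print.measurement_report <- function(x, ...) {
  cat("<measurement_report>\n")
  cat("  ", x$statement, "\n", sep = "")
  cat(sprintf("  numeric value: %.6g mL\n", x$volume_ml))
  if (!is.null(x$seg_sop_uid))
    cat("  references SEG:", x$seg_sop_uid, "\n")
  invisible(x)
}
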