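# Tag dictionary for the subset of the DICOM data dictionary this package
# reads and writes: CT Image Storage, Segmentation Storage, Comprehensive SR,
# plus the identifying tags handled by the anonymizer.

.qv_dict_raw <- c(
  "0008,0005", "CS", "SpecificCharacterSet",
  "0008,0008", "CS", "ImageType",
  "0008,0016", "UI", "SOPClassUID",
  "0008,0018", "UI", "SOPInstanceUID",
  "0008,0020", "DA", "StudyDate",
  "0008,0021", "DA", "SeriesDate",
  "0008,0023", "DA", "ContentDate",
  "0008,0030", "TM", "StudyTime",
  "0008,0031", "TM", "SeriesTime",
  "0008,0033", "TM", "ContentTime",
  "0008,0050", "SH", "AccessionNumber",
  "0008,0060", "CS", "Modality",
  "0008,0070", "LO", "Manufacturer",
  "0008,0080", "LO", "InstitutionName",
  "0008,0081", "ST", "InstitutionAddress",
  "0008,0090", "PN", "ReferringPhysicianName",
  "0008,0100", "SH", "CodeValue",
  "0008,0102", "SH", "CodingSchemeDesignator",
  "0008,0104", "LO", "CodeMeaning",
  "0008,1030", "LO", "StudyDescription",
  "0008,103E", "LO", "SeriesDescription",
  "0008,1050", "PN", "PerformingPhysicianName",
  "0008,1070", "PN", "OperatorsName",
  "0008,1090", "LO", "ManufacturerModelName",
  "0008,1115", "SQ", "ReferencedSeriesSequence",
  "0008,114A", "SQ", "ReferencedInstanceSequence",
  "0008,1150", "UI", "ReferencedSOPClassUID",
  "0008,1155", "UI", "ReferencedSOPInstanceUID",
  "0008,2112", "SQ", "SourceImageSequence",
  "0008,9124", "SQ", "DerivationImageSequence",
  "0010,0010", "PN", "PatientName",
  "0010,0020", "LO", "PatientID",
  "0010,0030", "DA", "PatientBirthDate",
  "0010,0040", "CS", "PatientSex",
  "0010,1010", "AS", "PatientAge",
  "0010,1040", "LO", "PatientAddress",
  "0010,2154", "SH", "PatientTelephoneNumbers",
  "0012,0062", "CS", "PatientIdentityRemoved",
  "0012,0063", "LO", "DeidentificationMethod",
  "0018,0050", "DS", "SliceThickness",
  "0018,0088", "DS", "SpacingBetweenSlices",
  "0018,1000", "LO", "DeviceSerialNumber",
  "0018,1030", "LO", "ProtocolName",
  "0020,000D", "UI", "StudyInstanceUID",
  "0020,000E", "UI", "SeriesInstanceUID",
  "0020,0010", "SH", "StudyID",
  "0020,0011", "IS", "SeriesNumber",
  "0020,0013", "IS", "InstanceNumber",
  "0020,0032", "DS", "ImagePositionPatient",
  "0020,0037", "DS", "ImageOrientationPatient",
  "0020,0052", "UI", "FrameOfReferenceUID",
  "0020,1040", "LO", "PositionReferenceIndicator",
  "0020,9111", "SQ", "FrameContentSequence",
  "0020,9113", "SQ", "PlanePositionSequence",
  "0020,9116", "SQ", "PlaneOrientationSequence",
  "0020,9157", "UL", "DimensionIndexValues",
  "0028,0002", "US", "SamplesPerPixel",
  "0028,0004", "CS", "PhotometricInterpretation",
  "0028,0008", "IS", "NumberOfFrames",
  "0028,0010", "US", "Rows",
  "0028,0011", "US", "Columns",
  "0028,0030", "DS", "PixelSpacing",
  "0028,0100", "US", "BitsAllocated",
  "0028,0101", "US", "BitsStored",
  "0028,0102", "US", "HighBit",
  "0028,0103", "US", "PixelRepresentation",
  "0028,1052", "DS", "RescaleIntercept",
  "0028,1053", "DS", "RescaleSlope",
  "0028,1054", "LO", "RescaleType",
  "0028,2110", "CS", "LossyImageCompression",
  "0028,9110", "SQ", "PixelMeasuresSequence",
  "0040,08EA", "SQ", "MeasurementUnitsCodeSequence",
  "0040,A010", "CS", "RelationshipType",
  "0040,A040", "CS", "ValueType",
  "0040,A043", "SQ", "ConceptNameCodeSequence",
  "0040,A050", "CS", "ContinuityOfContent",
  "0040,A160", "UT", "TextValue",
  "0040,A168", "SQ", "ConceptCodeSequence",
  "0040,A300", "SQ", "MeasuredValueSequence",
  "0040,A30A", "DS", "NumericValue",
  "0040,A375", "SQ", "CurrentRequestedProcedureEvidenceSequence",
  "0040,A491", "CS", "CompletionFlag",
  "0040,A493", "CS", "VerificationFlag",
  "0040,A730", "SQ", "ContentSequence",
  "0062,0001", "CS", "SegmentationType",
  "0062,0002", "SQ", "SegmentSequence",
  "0062,0003", "SQ", "SegmentedPropertyCategoryCodeSequence",
  "0062,0004", "US", "SegmentNumber",
  "0062,0005", "LO", "SegmentLabel",
  "0062,0008", "CS", "SegmentAlgorithmType",
  "0062,0009", "LO", "SegmentAlgorithmName",
  "0062,000A", "SQ", "SegmentIdentificationSequence",
  "0062,000B", "US", "ReferencedSegmentNumber",
  "0062,000D", "US", "RecommendedDisplayCIELabValue",
  "0062,000F", "SQ", "SegmentedPropertyTypeCodeSequence",
  "0070,0080", "CS", "ContentLabel",
  "0070,0081", "LO", "ContentDescription",
  "0070,0084", "PN", "ContentCreatorName",
  "5200,9229", "SQ", "SharedFunctionalGroupsSequence",
  "5200,9230", "SQ", "PerFrameFunctionalGroupsSequence",
  "7FE0,0010", "OW", "PixelData"
)

.qv_dict <- local({
  m <- matrix(.qv_dict_raw, ncol = 3L, byrow = TRUE)
  d <- data.frame(tag = m[, 1L], vr = m[, 2L], name = m[, 3L],
                  stringsAsFactors = FALSE)
  d$group <- strtoi(substr(d$tag, 1L, 4L), 16L)
  d$elem  <- strtoi(substr(d$tag, 6L, 9L), 16L)
  d
})

.qv_dict_by_name <- local({
  e <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(.qv_dict)))
    assign(.qv_dict$name[i], .qv_dict[i, ], envir = e)
  e
})

.qv_dict_by_tag <- local({
  e <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(.qv_dict)))
    assign(.qv_dict$tag[i], .qv_dict[i, ], envir = e)
  e
})

#' Look up a DICOM tag by keyword
#' @param name DICOM keyword, e.g. "PatientName".
#' @return list with fields tag ("GGGG,EEEE"), vr, name, group, elem.
#' @keywords internal
dcm_tag_info <- function(name) {
  info <- get0(name, envir = .qv_dict_by_name, inherits = FALSE)
  if (is.null(info)) qv_stop("qv_validation_error",
                             sprintf("unknown DICOM keyword '%s'", name))
  info
}

qv_tag_key <- function(group, elem) sprintf("%04X,%04X", group, elem)

qv_tag_name <- function(key) {
  info <- get0(key, envir = .qv_dict_by_tag, inherits = FALSE)
  if (is.null(info)) key else info$name
}
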