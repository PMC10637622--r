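#' DICOM SEG encoding and decoding
#'
#' A label volume is encoded as a binary (1 bit per voxel) multi-frame
#' Segmentation Storage object linked per-frame to the source CT instances,
#' and decoded back onto the full source grid for verification and
#' volumetry. Only slices containing at least one labeled voxel get a frame
#' (compact form); decoding re-inflates the full grid.
#'
#' @name qv-seg-codec
NULL

.QV_SEG_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.66.4"
.QV_CT_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.2"

# ---- sRGB <-> DICOM 16-bit CIELab ------------------------------------------
# DICOM stores a segment's recommended display color as CIELab scaled to
# 16 bits. The conversions below are exact inverses up to rounding; 8-bit
# sRGB values round-trip exactly because the 16-bit Lab grid is much finer.

.qv_srgb_to_xyz <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                            0.2126729, 0.7151522, 0.0721750,
                            0.0193339, 0.1191920, 0.9503041),
                          3L, 3L, byrow = TRUE)
.qv_white_d65 <- c(0.95047, 1.0, 1.08883)

#' Convert an 8-bit sRGB triple to DICOM 16-bit CIELab
#' @param rgb integer vector of 3 values in 0..255.
#' @return integer vector of 3 values in 0..65535 (L*, a*, b* scaled).
#' @export
rgb_to_cielab16 <- function(rgb) {
  rgb <- as.numeric(rgb)
  if (length(rgb) != 3L || any(rgb < 0) || any(rgb > 255))
    qv_stop("qv_validation_error", "rgb must be 3 values in 0..255",
            field = "rgb")
  c_ <- rgb / 255
  lin <- ifelse(c_ <= 0.04045, c_ / 12.92, ((c_ + 0.055) / 1.055)^2.4)
  xyz <- as.vector(.qv_srgb_to_xyz %*% lin) / .qv_white_d65
  delta <- 6 / 29
  f <- ifelse(xyz > delta^3, xyz^(1 / 3), xyz / (3 * delta^2) + 4 / 29)
  lab <- c(116 * f[2] - 16, 500 * (f[1] - f[2]), 200 * (f[2] - f[3]))
  as.integer(round(c(lab[1] * 65535 / 100,
                     (lab[2] + 128) * 65535 / 255,
                     (lab[3] + 128) * 65535 / 255)))
}

#' Convert DICOM 16-bit CIELab back to 8-bit sRGB
#' @param lab16 integer vector of 3 values in 0..65535.
#' @return integer vector of 3 sRGB values in 0..255.
#' @export
cielab16_to_rgb <- function(lab16) {
  lab16 <- as.numeric(lab16)
  L <- lab16[1] * 100 / 65535
  a <- lab16[2] * 255 / 65535 - 128
  b <- lab16[3] * 255 / 65535 - 128
  delta <- 6 / 29
  fy <- (L + 16) / 116
  fx <- fy + a / 500
  fz <- fy - b / 200
  finv <- function(t) ifelse(t > delta, t^3, 3 * delta^2 * (t - 4 / 29))
  xyz <- finv(c(fx, fy, fz)) * .qv_white_d65
  lin <- as.vector(solve(.qv_srgb_to_xyz) %*% xyz)
  c_ <- ifelse(lin <= 0.0031308, 12.92 * lin,
               1.055 * pmax(lin, 0)^(1 / 2.4) - 0.055)
  pmin(255L, pmax(0L, as.integer(round(c_ * 255))))
}

# ---- segment descriptor -----------------------------------------------------

#' Segment descriptor: label, coded meaning, display color
#'
#' @param label free-text segment label, e.g. "hemorrhage".
#' @param coded_category,coded_type coded concept as a list with elements
#'   \code{scheme}, \code{value}, \code{meaning}.
#' @param rgb display color as 3 integers 0..255.
#' @param segment_number positive integer (>= 1).
#' @return A \code{segment_descriptor}.
#' @export
segment_descriptor <- function(label,
                               coded_category = list(scheme = "SCT",
                                                     value = "49755003",
                                                     meaning = "Morphologically altered structure"),
                               coded_type = list(scheme = "SCT",
                                                 value = "400177003",
                                                 meaning = "Neoplasm and/or hamartoma"),
                               rgb = c(255L, 0L, 0L),
                               segment_number = 1L) {
  rgb <- as.integer(rgb)
  if (length(rgb) != 3L || any(is.na(rgb)) || any(rgb < 0L) || any(rgb > 255L))
    qv_stop("qv_validation_error",
            "display color components must be integers in 0..255",
            field = "rgb")
  segment_number <- as.integer(segment_number)
  if (is.na(segment_number) || segment_number < 1L)
    qv_stop("qv_validation_error", "segment_number must be >= 1",
            field = "segment_number")
  for (cc in list(coded_category, coded_type))
    if (!all(c("scheme", "value", "meaning") %in% names(cc)))
      qv_stop("qv_validation_error",
              "coded concepts need scheme/value/meaning", field = "coded")
  structure(list(label = as.character(label),
                 coded_category = coded_category, coded_type = coded_type,
                 rgb = rgb, segment_number = segment_number),
            class = "segment_descriptor")
}

#' Load a segment-metadata JSON file
#'
#' Schema (keys): \code{label} (required), \code{rgb} (default
#' \code{[255, 0, 0]}), \code{coded_category}, \code{coded_type} (each an
#' object with \code{scheme}/\code{value}/\code{meaning}; documented
#' defaults applied when absent), \code{segment_number} (default 1).
#' Unknown keys are rejected.
#'
#' @param path path to the JSON file.
#' @return A \code{segment_descriptor}.
#' @export
load_segment_metadata <- function(path) {
  if (!file.exists(path))
    qv_stop("qv_parse_error", sprintf("no such file: %s", path))
  meta <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                   error = function(e)
                     qv_stop("qv_parse_error",
                             sprintf("malformed segment metadata %s: %s",
                                     path, conditionMessage(e))))
  allowed <- c("label", "rgb", "coded_category", "coded_type",
               "segment_number")
  unknown <- setdiff(names(meta), allowed)
  if (length(unknown))
    qv_stop("qv_validation_error",
            sprintf("unknown segment-metadata key(s): %s",
                    paste(unknown, collapse = ", ")))
  if (is.null(meta$label))
    qv_stop("qv_validation_error", "segment metadata must name a label")
  args <- list(label = meta$label)
  if (!is.null(meta$rgb)) args$rgb <- meta$rgb
  if (!is.null(meta$coded_category)) args$coded_category <- as.list(meta$coded_category)
  if (!is.null(meta$coded_type)) args$coded_type <- as.list(meta$coded_type)
  if (!is.null(meta$segment_number)) args$segment_number <- meta$segment_number
  do.call(segment_descriptor, args)
}

# ---- geometry of a sorted stack (tags only, no pixel decode) ----------------

qv_stack_geometry <- function(source) {
  s <- sort_slices(source)
  first <- s$instances[[1L]]
  ps <- dcm_get(first, "PixelSpacing")
  iop <- dcm_get(first, "ImageOrientationPatient")
  r_dir <- iop[1:3]; c_dir <- iop[4:6]; n_dir <- qv_slice_normal(iop)
  origin <- dcm_get(first, "ImagePositionPatient")
  a_lps <- cbind(c(r_dir * ps[2L], 0), c(c_dir * ps[1L], 0),
                 c(n_dir * s$slice_step_mm, 0), c(origin, 1))
  list(sorted = s$instances, step = s$slice_step_mm,
       rows = as.integer(dcm_get(first, "Rows")),
       cols = as.integer(dcm_get(first, "Columns")),
       ps = ps, iop = iop,
       affine = diag(c(-1, -1, 1, 1)) %*% a_lps,
       sop_uids = vapply(s$instances, dcm_get, character(1),
                         name = "SOPInstanceUID"))
}

qv_code_item <- function(code) {
  it <- dcm_dataset()
  it <- dcm_set(it, "CodeValue", code$value)
  it <- dcm_set(it, "CodingSchemeDesignator", code$scheme)
  dcm_set(it, "CodeMeaning", code$meaning)
}

# ---- encode -----------------------------------------------------------------

#' Encode a label mask as a DICOM SEG object
#'
#' Produces a binary Segmentation Storage dataset: one bit-packed frame per
#' slice containing at least one labeled voxel, each frame carrying a
#' derivation reference to its source SOP instance and the slice's plane
#' position. The study UID is inherited from the source; new SOP and series
#' UIDs are minted under \code{uid_root}. Any nonzero mask value counts as
#' foreground.
#'
#' @param mask label \code{geometric_volume}, grid-congruent with the
#'   assembled source series (shape equal, affine within 1e-4).
#' @param source list of source CT \code{dicom_dataset}s (one series).
#' @param desc a \code{segment_descriptor}.
#' @param uid_root root for minted UIDs.
#' @return A \code{dicom_dataset} holding the SEG object.
#' @export
encode_seg <- function(mask, source, desc, uid_root = qv_default_uid_root()) {
  stopifnot(inherits(mask, "geometric_volume"),
            inherits(desc, "segment_descriptor"))
  g <- qv_stack_geometry(source)
  dims <- dim(mask$voxels)
  if (!identical(dims, c(g$cols, g$rows, length(g$sorted))))
    qv_stop("qv_geometry_error",
            sprintf("mask shape %s does not match source grid %s",
                    paste(dims, collapse = "x"),
                    paste(c(g$cols, g$rows, length(g$sorted)),
                          collapse = "x")))
  if (max(abs(mask$affine - g$affine)) > 1e-4)
    qv_stop("qv_geometry_error", "mask affine does not match source grid")
  fg <- mask$voxels > 0
  if (!any(fg))
    qv_stop("qv_empty_segmentation_error",
            "mask has no labeled voxel; nothing to encode")

  frame_slices <- which(apply(fg, 3L, any))
  nframes <- length(frame_slices)
  bits <- unlist(lapply(frame_slices, function(s) as.vector(fg[, , s])),
                 use.names = FALSE)
  pad <- (-length(bits)) %% 8L
  packed <- packBits(c(bits, rep(FALSE, pad)), type = "raw")

  per_frame <- lapply(seq_len(nframes), function(f) {
    s <- frame_slices[f]
    src <- g$sorted[[s]]
    fc <- dcm_dataset()
    fc <- dcm_set(fc, "DimensionIndexValues", f)
    si <- dcm_dataset()
    si <- dcm_set(si, "ReferencedSOPClassUID", dcm_get(src, "SOPClassUID"))
    si <- dcm_set(si, "ReferencedSOPInstanceUID",
                  dcm_get(src, "SOPInstanceUID"))
    di <- dcm_dataset()
    di <- dcm_set(di, "SourceImageSequence", list(si))
    pp <- dcm_dataset()
    pp <- dcm_set(pp, "ImagePositionPatient",
                  dcm_get(src, "ImagePositionPatient"))
    sid <- dcm_dataset()
    sid <- dcm_set(sid, "ReferencedSegmentNumber", desc$segment_number)
    it <- dcm_dataset()
    it <- dcm_set(it, "FrameContentSequence", list(fc))
    it <- dcm_set(it, "DerivationImageSequence", list(di))
    it <- dcm_set(it, "PlanePositionSequence", list(pp))
    dcm_set(it, "SegmentIdentificationSequence", list(sid))
  })

  po <- dcm_dataset()
  po <- dcm_set(po, "ImageOrientationPatient", g$iop)
  pm <- dcm_dataset()
  pm <- dcm_set(pm, "PixelSpacing", g$ps)
  pm <- dcm_set(pm, "SliceThickness",
                dcm_get(g$sorted[[1L]], "SliceThickness", g$step))
  pm <- dcm_set(pm, "SpacingBetweenSlices", g$step)
  shared_item <- dcm_dataset()
  shared_item <- dcm_set(shared_item, "PlaneOrientationSequence", list(po))
  shared_item <- dcm_set(shared_item, "PixelMeasuresSequence", list(pm))

  seg_item <- dcm_dataset()
  seg_item <- dcm_set(seg_item, "SegmentNumber", desc$segment_number)
  seg_item <- dcm_set(seg_item, "SegmentLabel", desc$label)
  seg_item <- dcm_set(seg_item, "SegmentAlgorithmType", "AUTOMATIC")
  seg_item <- dcm_set(seg_item, "SegmentAlgorithmName", "qvbridge")
  seg_item <- dcm_set(seg_item, "RecommendedDisplayCIELabValue",
                      rgb_to_cielab16(desc$rgb))
  seg_item <- dcm_set(seg_item, "SegmentedPropertyCategoryCodeSequence",
                      list(qv_code_item(desc$coded_category)))
  seg_item <- dcm_set(seg_item, "SegmentedPropertyTypeCodeSequence",
                      list(qv_code_item(desc$coded_type)))

  ref_instances <- lapply(g$sorted[frame_slices], function(src) {
    it <- dcm_dataset()
    it <- dcm_set(it, "ReferencedSOPClassUID", dcm_get(src, "SOPClassUID"))
    dcm_set(it, "ReferencedSOPInstanceUID", dcm_get(src, "SOPInstanceUID"))
  })
  ref_series <- dcm_dataset()
  ref_series <- dcm_set(ref_series, "SeriesInstanceUID",
                        dcm_get(g$sorted[[1L]], "SeriesInstanceUID"))
  ref_series <- dcm_set(ref_series, "ReferencedInstanceSequence",
                        ref_instances)

  ds <- dcm_dataset()
  ds <- dcm_set(ds, "SOPClassUID", .QV_SEG_SOP_CLASS)
  ds <- dcm_set(ds, "SOPInstanceUID", new_uid(uid_root))
  ds <- dcm_set(ds, "StudyInstanceUID",
                dcm_get(g$sorted[[1L]], "StudyInstanceUID"))
  ds <- dcm_set(ds, "SeriesInstanceUID", new_uid(uid_root))
  frame_ref <- dcm_get(g$sorted[[1L]], "FrameOfReferenceUID")
  if (!is.null(frame_ref)) ds <- dcm_set(ds, "FrameOfReferenceUID", frame_ref)
  ds <- dcm_set(ds, "Modality", "SEG")
  ds <- dcm_set(ds, "SeriesDescription",
                paste0(desc$label, " segmentation"))
  ds <- dcm_set(ds, "SeriesNumber", 300L)
  ds <- dcm_set(ds, "InstanceNumber", 1L)
  ds <- dcm_set(ds, "ImageType", c("DERIVED", "PRIMARY"))
  ds <- dcm_set(ds, "ContentDate", format(Sys.Date(), "%Y%m%d"))
  ds <- dcm_set(ds, "ContentTime", format(Sys.time(), "%H%M%S"))
  ds <- dcm_set(ds, "ContentLabel", "SEGMENTATION")
  ds <- dcm_set(ds, "ContentDescription", "qvbridge segmentation")
  ds <- dcm_set(ds, "ContentCreatorName", "qvbridge")
  ds <- dcm_set(ds, "SamplesPerPixel", 1L)
  ds <- dcm_set(ds, "PhotometricInterpretation", "MONOCHROME2")
  ds <- dcm_set(ds, "Rows", g$rows)
  ds <- dcm_set(ds, "Columns", g$cols)
  ds <- dcm_set(ds, "BitsAllocated", 1L)
  ds <- dcm_set(ds, "BitsStored", 1L)
  ds <- dcm_set(ds, "HighBit", 0L)
  ds <- dcm_set(ds, "PixelRepresentation", 0L)
  ds <- dcm_set(ds, "NumberOfFrames", nframes)
  ds <- dcm_set(ds, "LossyImageCompression", "00")
  ds <- dcm_set(ds, "SegmentationType", "BINARY")
  ds <- dcm_set(ds, "SegmentSequence", list(seg_item))
  ds <- dcm_set(ds, "SharedFunctionalGroupsSequence", list(shared_item))
  ds <- dcm_set(ds, "PerFrameFunctionalGroupsSequence", per_frame)
  ds <- dcm_set(ds, "ReferencedSeriesSequence", list(ref_series))
  ds$elements[["7FE0,0010"]] <- list(vr = "OB", value = packed)
  ds
}

# ---- decode -----------------------------------------------------------------

#' Per-frame source references of a SEG object
#' @param seg a SEG \code{dicom_dataset}.
#' @return Character vector of referenced SOP instance UIDs, one per frame.
#' @export
seg_frame_references <- function(seg) {
  per_frame <- dcm_get(seg, "PerFrameFunctionalGroupsSequence")
  if (is.null(per_frame) || length(per_frame) == 0L)
    qv_stop("qv_linkage_error", "SEG object has no per-frame references")
  vapply(per_frame, function(it) {
    di <- dcm_get(it, "DerivationImageSequence")
    src <- dcm_get(di[[1L]], "SourceImageSequence")
    dcm_get(src[[1L]], "ReferencedSOPInstanceUID")
  }, character(1))
}

#' Unpack the bit-packed frames of a SEG object
#' @param seg a SEG \code{dicom_dataset}.
#' @return Integer vector of 0/1 of length frames x rows x cols, in frame
#'   order then row-major pixel order within each frame.
#' @export
seg_unpack_bits <- function(seg) {
  nframes <- as.integer(dcm_get(seg, "NumberOfFrames"))
  rows <- as.integer(dcm_get(seg, "Rows"))
  cols <- as.integer(dcm_get(seg, "Columns"))
  packed <- dcm_get(seg, "PixelData")
  nbits <- nframes * rows * cols
  if (length(packed) * 8L < nbits)
    qv_stop("qv_format_error", "SEG pixel data shorter than frame count implies")
  as.integer(rawToBits(packed))[seq_len(nbits)]
}

#' Decode a DICOM SEG object onto its source grid
#'
#' Re-inflates the compact per-frame representation to a full label volume
#' on the assembled source grid; slices without a frame are zero.
#'
#' @param seg a SEG \code{dicom_dataset} produced by \code{\link{encode_seg}}
#'   (or any single-segment binary SEG using per-frame derivation
#'   references).
#' @param source list of source CT \code{dicom_dataset}s.
#' @return A binary label \code{geometric_volume} with the source affine.
#' @export
decode_seg <- function(seg, source) {
  g <- qv_stack_geometry(source)
  refs <- seg_frame_references(seg)
  slice_idx <- match(refs, g$sop_uids)
  if (any(is.na(slice_idx)))
    qv_stop("qv_linkage_error",
            sprintf("SEG frame references unknown SOP instance(s): %s",
                    paste(refs[is.na(slice_idx)], collapse = ", ")))
  rows <- as.integer(dcm_get(seg, "Rows"))
  cols <- as.integer(dcm_get(seg, "Columns"))
  if (rows != g$rows || cols != g$cols)
    qv_stop("qv_geometry_error", "SEG matrix size does not match source")
  bits <- seg_unpack_bits(seg)
  nframes <- length(refs)
  mask <- array(0L, c(g$cols, g$rows, length(g$sorted)))
  fsize <- rows * cols
  for (f in seq_len(nframes)) {
    frame <- bits[((f - 1L) * fsize + 1L):(f * fsize)]
    mask[, , slice_idx[f]] <- frame
  }
  geometric_volume(mask, g$affine, source_sop_uids = g$sop_uids,
                   study_uid = dcm_get(seg, "StudyInstanceUID"),
                   series_uid = dcm_get(seg, "SeriesInstanceUID"))
}

#' Validate the UID tree linking a SEG to its source series
#'
#' Checks that the SEG's study UID equals the source study UID and that
#' every frame reference resolves to a source SOP instance.
#'
#' @param seg a SEG \code{dicom_dataset}.
#' @param source list of source CT \code{dicom_dataset}s.
#' @return TRUE invisibly; signals \code{qv_linkage_error} otherwise.
#' @export
validate_seg_linkage <- function(seg, source) {
  src_study <- unique(vapply(source, dcm_get, character(1),
                             name = "StudyInstanceUID"))
  if (length(src_study) != 1L || !identical(dcm_get(seg, "StudyInstanceUID"),
                                            src_study))
    qv_stop("qv_linkage_error", "SEG study UID does not match source study")
  sops <- vapply(source, dcm_get, character(1), name = "SOPInstanceUID")
  refs <- seg_frame_references(seg)
  missing <- setdiff(refs, sops)
  if (length(missing))
    qv_stop("qv_linkage_error",
            sprintf("unresolved frame reference(s): %s",
                    paste(missing, collapse = ", ")))
  invisible(TRUE)
}
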