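#' In-memory DICOM dataset
#'
#' A \code{dicom_dataset} is an ordered collection of data elements keyed by
#' tag ("GGGG,EEEE"). Each element stores its value representation (VR) and a
#' parsed R value: character vectors for string VRs, numeric vectors for
#' DS/IS/US/SS/UL/SL/FD/FL, raw vectors for OB/OW, and lists of nested
#' \code{dicom_dataset} items for SQ. Values are encoded to DICOM wire form
#' only at write time.
#'
#' @param ... ignored.
#' @return An empty \code{dicom_dataset}.
#' @export
dcm_dataset <- function(...) {
  structure(list(elements = list()), class = "dicom_dataset")
}

#' Set a data element by keyword
#'
#' @param ds a \code{dicom_dataset}.
#' @param name DICOM keyword (must be in the package dictionary).
#' @param value the R value (see \code{\link{dcm_dataset}} for types).
#' @return The modified dataset.
#' @export
dcm_set <- function(ds, name, value) {
  info <- dcm_tag_info(name)
  dcm_set_tag(ds, info$group, info$elem, info$vr, value)
}

#' Set a data element by explicit tag
#'
#' Used for tags outside the shipped dictionary (e.g. private tags in tests).
#'
#' @param ds a \code{dicom_dataset}.
#' @param group,elem integer tag components.
#' @param vr two-letter value representation.
#' @param value the R value.
#' @return The modified dataset.
#' @export
dcm_set_tag <- function(ds, group, elem, vr, value) {
  stopifnot(inherits(ds, "dicom_dataset"))
  key <- qv_tag_key(group, elem)
  ds$elements[[key]] <- list(vr = vr, value = value)
  ds
}

#' Get a data element value by keyword
#'
#' @param ds a \code{dicom_dataset}.
#' @param name DICOM keyword.
#' @param default value returned when the element is absent.
#' @return The parsed element value, or \code{default}.
#' @export
dcm_get <- function(ds, name, default = NULL) {
  info <- dcm_tag_info(name)
  el <- ds$elements[[info$tag]]
  if (is.null(el)) default else el$value
}

#' @rdname dcm_get
#' @export
dcm_has <- function(ds, name) {
  info <- dcm_tag_info(name)
  !is.null(ds$elements[[info$tag]])
}

#' Delete a data element by keyword
#' @inheritParams dcm_get
#' @return The modified dataset.
#' @export
dcm_del <- function(ds, name) {
  info <- dcm_tag_info(name)
  ds$elements[[info$tag]] <- NULL
  ds
}

#' Tags present in a dataset
#' @param ds a \code{dicom_dataset}.
#' @return Character vector of "GGGG,EEEE" keys in storage order.
#' @export
dcm_tags <- function(ds) names(ds$elements)

#' @export
print.dicom_dataset <- function(x, ...) {
  keys <- sort(names(x$elements))
  cat(sprintf("<dicom_dataset: %d elements>\n", length(keys)))
  for (k in keys) {
    el <- x$elements[[k]]
    v <- el$value
    desc <- if (el$vr == "SQ") {
      sprintf("sequence of %d item(s)", length(v))
    } else if (is.raw(v)) {
      sprintf("%d bytes", length(v))
    } else {
      paste(utils::head(as.character(v), 6L), collapse = "\\")
    }
    cat(sprintf("  (%s) %-28s %s  %s\n", k, qv_tag_name(k), el$vr, desc))
  }
  invisible(x)
}

# ---- helpers for image instances -------------------------------------------

#' Decode the stored pixel matrix of a CT instance
#'
#' Returns the raw stored values (before rescale) as an integer matrix indexed
#' \code{[column, row]}, i.e. the first index runs along a displayed image row.
#'
#' @param inst a \code{dicom_dataset} holding a single-frame image.
#' @return Integer matrix of dim \code{c(Columns, Rows)}.
#' @export
dcm_pixel_matrix <- function(inst) {
  rows <- dcm_get(inst, "Rows")
  cols <- dcm_get(inst, "Columns")
  bits <- dcm_get(inst, "BitsAllocated")
  signed <- identical(as.integer(dcm_get(inst, "PixelRepresentation", 0L)), 1L)
  px <- dcm_get(inst, "PixelData")
  if (is.null(rows) || is.null(cols) || is.null(px))
    qv_stop("qv_format_error", "instance has no decodable pixel data")
  if (bits != 16L)
    qv_stop("qv_format_error", "only 16-bit image pixel data is supported")
  n <- as.integer(rows) * as.integer(cols)
  v <- readBin(px, integer(), n = n, size = 2L, signed = signed,
               endian = "little")
  matrix(v, nrow = as.integer(cols), ncol = as.integer(rows))
}

#' Rescaled Hounsfield-unit matrix of a CT instance
#' @inheritParams dcm_pixel_matrix
#' @return Numeric matrix (HU), same layout as \code{dcm_pixel_matrix}.
#' @export
dcm_hu_matrix <- function(inst) {
  slope <- dcm_get(inst, "RescaleSlope", 1)
  intercept <- dcm_get(inst, "RescaleIntercept", 0)
  dcm_pixel_matrix(inst) * slope + intercept
}

#' Encode an integer matrix as 16-bit pixel data
#' @param m integer matrix indexed \code{[column, row]}.
#' @return Raw vector in little-endian 16-bit wire form.
#' @keywords internal
qv_encode_pixels16 <- function(m) {
  v <- as.integer(m)
  if (any(v < -32768L | v > 32767L))
    qv_stop("qv_validation_error", "pixel values out of signed 16-bit range")
  writeBin(v, raw(), size = 2L, endian = "little")
}

#' Validate the UID triple of an instance
#' @param inst a \code{dicom_dataset}.
#' @return TRUE invisibly; signals \code{qv_validation_error} otherwise.
#' @export
dcm_validate_uids <- function(inst) {
  for (nm in c("StudyInstanceUID", "SeriesInstanceUID", "SOPInstanceUID")) {
    uid <- dcm_get(inst, nm)
    if (is.null(uid) || !is_valid_uid(uid))
      qv_stop("qv_validation_error",
              sprintf("missing or syntactically invalid %s", nm), field = nm)
  }
  invisible(TRUE)
}
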