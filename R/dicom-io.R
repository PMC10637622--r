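# DICOM part-10 file I/O, Explicit VR Little Endian only.
#
# The writer emits defined lengths everywhere (including sequences and
# items); the reader additionally accepts undefined-length sequences and
# items with delimitation tags, since those are common in files produced by
# other toolkits.

.QV_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.QV_IMPL_CLASS_UID <- "2.25.847190.1.1"
.QV_LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")
.QV_STRING_VRS <- c("AE", "AS", "CS", "DA", "DT", "LO", "LT", "PN",
                    "SH", "ST", "TM", "UI", "UT", "UC", "UR")

# ---- encoding ---------------------------------------------------------------

qv_enc_u16 <- function(x) {
  x <- as.integer(x)
  x <- ifelse(x > 32767L, x - 65536L, x)
  writeBin(x, raw(), size = 2L, endian = "little")
}

qv_enc_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

#' Format numbers as DICOM decimal strings
#' @param x numeric vector.
#' @return character vector, each at most 16 characters.
#' @keywords internal
qv_format_ds <- function(x) {
  s <- vapply(x, function(v) sprintf("%.10g", v), character(1))
  long <- nchar(s) > 16L
  if (any(long))
    s[long] <- vapply(x[long], function(v) sprintf("%.8g", v), character(1))
  s
}

qv_enc_value <- function(vr, value) {
  if (vr == "SQ") {
    parts <- lapply(value, function(item) {
      body <- qv_enc_dataset(item)
      c(qv_enc_u16(0xFFFE), qv_enc_u16(0xE000), qv_enc_u32(length(body)), body)
    })
    return(do.call(c, c(parts, list(raw(0)))))
  }
  if (vr %in% c("OB", "OW", "UN")) {
    b <- as.raw(value)
    if (length(b) %% 2L == 1L) b <- c(b, as.raw(0L))
    return(b)
  }
  if (vr %in% c("US",        "SS")) return(qv_enc_u16(value))
  if (vr %in% c("UL", "SL")) return(qv_enc_u32(value))
  if (vr == "FD") return(writeBin(as.double(value), raw(), size = 8L, endian = "little"))
  if (vr == "FL") return(writeBin(as.double(value), raw(), size = 4L, endian = "little"))
  s <- if (vr == "DS") qv_format_ds(as.numeric(value))
       else if (vr == "IS") sprintf("%d", as.integer(value))
       else as.character(value)
  b <- charToRaw(paste(s, collapse = "\\"))
  if (length(b) %% 2L == 1L)
    b <- c(b, if (vr == "UI") as.raw(0L) else charToRaw(" "))
  b
}

qv_enc_element <- function(group, elem, vr, value) {
  body <- qv_enc_value(vr, value)
  hdr <- c(qv_enc_u16(group), qv_enc_u16(elem), charToRaw(vr))
  if (vr %in% .QV_LONG_VRS) {
    c(hdr, as.raw(c(0L, 0L)), qv_enc_u32(length(body)), body)
  } else {
    if (length(body) > 65534L)
      qv_stop("qv_format_error",
              sprintf("value too long for short-form VR %s", vr))
    c(hdr, qv_enc_u16(length(body)), body)
  }
}

qv_enc_dataset <- function(ds) {
  keys <- sort(names(ds$elements))
  parts <- lapply(keys, function(k) {
    el <- ds$elements[[k]]
    group <- strtoi(substr(k, 1L, 4L), 16L)
    elem <- strtoi(substr(k, 6L, 9L), 16L)
    qv_enc_element(group, elem, el$vr, el$value)
  })
  do.call(c, c(parts, list(raw(0))))
}

#' Write a dataset as a DICOM part-10 file
#'
#' Writes Explicit VR Little Endian with a standard 128-byte preamble and
#' file meta information group derived from the dataset's SOP class and
#' instance UIDs.
#'
#' @param ds a \code{dicom_dataset} containing at least SOPClassUID and
#'   SOPInstanceUID.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_dicom <- function(ds, path) {
  sop_class <- dcm_get(ds, "SOPClassUID")
  sop_inst <- dcm_get(ds, "SOPInstanceUID")
  if (is.null(sop_class) || is.null(sop_inst))
    qv_stop("qv_validation_error", "dataset lacks SOPClassUID/SOPInstanceUID")
  meta <- c(
    qv_enc_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    qv_enc_element(0x0002, 0x0002, "UI", sop_class),
    qv_enc_element(0x0002, 0x0003, "UI", sop_inst),
    qv_enc_element(0x0002, 0x0010, "UI", .QV_TS_EXPLICIT_LE),
    qv_enc_element(0x0002, 0x0012, "UI", .QV_IMPL_CLASS_UID),
    qv_enc_element(0x0002, 0x0013, "SH", "QVBRIDGE_01")
  )
  out <- c(raw(128L), charToRaw("DICM"),
           qv_enc_element(0x0002, 0x0000, "UL", length(meta)),
           meta, qv_enc_dataset(ds))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}

# ---- decoding ---------------------------------------------------------------

qv_ru16 <- function(r, p) as.integer(r[p]) + 256L * as.integer(r[p + 1L])

qv_ru32 <- function(r, p) {
  as.numeric(r[p]) + 256 * as.numeric(r[p + 1L]) +
    65536 * as.numeric(r[p + 2L]) + 16777216 * as.numeric(r[p + 3L])
}

qv_need <- function(r, p, n) {
  if (p + n - 1L > length(r))
    qv_stop("qv_format_error", "truncated DICOM stream")
}

qv_parse_string <- function(bytes, vr) {
  # strip trailing padding (space, NUL)
  n <- length(bytes)
  while (n > 0L && bytes[n] %in% as.raw(c(0x00, 0x20))) n <- n - 1L
  if (n == 0L) return(character(0))
  s <- rawToChar(bytes[seq_len(n)])
  strsplit(s, "\\", fixed = TRUE)[[1L]]
}

qv_parse_value <- function(bytes, vr) {
  if (vr %in% c("OB", "OW", "OF", "UN")) return(bytes)
  if (vr == "US") return(readBin(bytes, integer(), n = length(bytes) %/% 2L,
                                 size = 2L, signed = FALSE, endian = "little"))
  if (vr == "SS") return(readBin(bytes, integer(), n = length(bytes) %/% 2L,
                                 size = 2L, signed = TRUE, endian = "little"))
  if (vr %in% c("UL", "SL")) {
    v <- readBin(bytes, integer(), n = length(bytes) %/% 4L, size = 4L,
                 endian = "little")
    if (vr == "UL") v <- ifelse(v < 0L, as.numeric(v) + 4294967296, as.numeric(v))
    return(v)
  }
  if (vr == "FD") return(readBin(bytes, double(), n = length(bytes) %/% 8L,
                                 size = 8L, endian = "little"))
  if (vr == "FL") return(readBin(bytes, double(), n = length(bytes) %/% 4L,
                                 size = 4L, endian = "little"))
  s <- qv_parse_string(bytes, vr)
  if (vr %in% c("DS", "IS")) return(as.numeric(s))
  s
}

# parse items of a sequence; returns list(items, pos just past the sequence)
qv_parse_sq <- function(r, p, len) {
  items <- list()
  undefined <- len >= 4294967295
  end <- if (undefined) length(r) + 1L else p + as.integer(len)
  while (p < end) {
    qv_need(r, p, 8L)
    g <- qv_ru16(r, p); e <- qv_ru16(r, p + 2L)
    ilen <- qv_ru32(r, p + 4L)
    p <- p + 8L
    if (g == 0xFFFE && e == 0xE0DD) break        # sequence delimiter
    if (!(g == 0xFFFE && e == 0xE000))
      qv_stop("qv_format_error", "malformed sequence: expected item tag")
    if (ilen >= 4294967295) {
      res <- qv_parse_dataset(r, p, length(r) + 1L, stop_at_item_delim = TRUE)
    } else {
      qv_need(r, p, as.integer(ilen))
      res <- qv_parse_dataset(r, p, p + as.integer(ilen),
                              stop_at_item_delim = FALSE)
    }
    items[[length(items) + 1L]] <- structure(list(elements = res$elements),
                                             class = "dicom_dataset")
    p <- res$pos
  }
  list(items = items, pos = p)
}

qv_parse_dataset <- function(r, p, end, stop_at_item_delim = FALSE) {
  elements <- list()
  while (p < end) {
    qv_need(r, p, 8L)
    group <- qv_ru16(r, p); elem <- qv_ru16(r, p + 2L)
    if (stop_at_item_delim && group == 0xFFFE && elem == 0xE00D) {
      p <- p + 8L
      break
    }
    vr <- rawToChar(r[(p + 4L):(p + 5L)])
    if (vr %in% .QV_LONG_VRS) {
      qv_need(r, p, 12L)
      len <- qv_ru32(r, p + 8L)
      p <- p + 12L
    } else {
      len <- qv_ru16(r, p + 6L)
      p <- p + 8L
    }
    key <- qv_tag_key(group, elem)
    if (vr == "SQ") {
      sq <- qv_parse_sq(r, p, len)
      elements[[key]] <- list(vr = vr, value = sq$items)
      p <- sq$pos
    } else {
      if (len >= 4294967295)
        qv_stop("qv_format_error",
                "undefined length outside a sequence is not supported")
      len <- as.integer(len)
      qv_need(r, p, len)
      bytes <- if (len > 0L) r[p:(p + len - 1L)] else raw(0)
      elements[[key]] <- list(vr = vr, value = qv_parse_value(bytes, vr))
      p <- p + len
    }
  }
  list(elements = elements, pos = p)
}

#' Read a DICOM part-10 file
#'
#' Only the Explicit VR Little Endian transfer syntax is supported; any other
#' syntax, a missing "DICM" magic, or a truncated stream raises a
#' \code{qv_format_error}.
#'
#' @param path file path.
#' @return A \code{dicom_dataset} (file meta group excluded).
#' @export
read_dicom <- function(path) {
  if (!file.exists(path))
    qv_stop("qv_format_error", sprintf("no such file: %s", path))
  r <- readBin(path, raw(), n = file.size(path))
  if (length(r) < 134L || rawToChar(r[129:132]) != "DICM")
    qv_stop("qv_format_error", sprintf("not a DICOM part-10 file: %s", path))
  p <- 133L
  # file meta group length element
  qv_need(r, p, 12L)
  if (!(qv_ru16(r, p) == 0x0002 && qv_ru16(r, p + 2L) == 0x0000))
    qv_stop("qv_format_error", "missing file meta group length")
  glen_len <- qv_ru16(r, p + 6L)
  glen <- qv_ru32(r, p + 8L)
  p <- p + 8L + glen_len
  meta <- qv_parse_dataset(r, p, p + as.integer(glen))
  ts_el <- meta$elements[["0002,0010"]]
  if (is.null(ts_el) || !identical(ts_el$value, .QV_TS_EXPLICIT_LE))
    qv_stop("qv_format_error",
            "unsupported transfer syntax (only Explicit VR Little Endian)")
  body <- qv_parse_dataset(r, meta$pos, length(r) + 1L)
  structure(list(elements = body$elements), class = "dicom_dataset")
}

#' Read every DICOM file in a directory
#' @param dir directory containing part-10 files.
#' @param pattern filename filter (default "\\.dcm$").
#' @return List of \code{dicom_dataset}, named by filename.
#' @export
read_dicom_dir <- function(dir, pattern = "\\.dcm$") {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  out <- lapply(files, read_dicom)
  names(out) <- basename(files)
  out
}
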