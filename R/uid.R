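#' DICOM unique identifiers
#'
#' UIDs are dotted-decimal strings (max 64 characters). New UIDs are minted
#' under an organizational root; uniqueness within a session is guaranteed by
#' a process-wide counter combined with seedable random material, so phantom
#' generation is reproducible while repeated calls still yield fresh UIDs.
#'
#' @name qv-uid
#' @keywords internal
NULL

# session-wide state: counter for minted UIDs
.qv_uid_state <- new.env(parent = emptyenv())
.qv_uid_state$counter <- 0L

#' Default organizational UID root
#' @return character scalar, a dotted-decimal UID prefix ending in ".".
#' @export
qv_default_uid_root <- function() "2.25.847190."

#' Mint a new DICOM UID
#'
#' @param root UID root (dotted decimal, trailing dot added if missing).
#' @return A syntactically valid UID string of at most 64 characters.
#' @export
new_uid <- function(root = qv_default_uid_root()) {
  if (!grepl("\\.$", root)) root <- paste0(root, ".")
  .qv_uid_state$counter <- .qv_uid_state$counter + 1L
  # random component comes from the session RNG: under set.seed() the
  # sequence is reproducible, while the counter keeps every UID distinct
  rnd <- paste0(c(sample(1:9, 1), sample(0:9, 11, replace = TRUE)),
                collapse = "")
  uid <- paste0(root, rnd, ".", .qv_uid_state$counter)
  if (nchar(uid) > 64) qv_stop("qv_validation_error", "generated UID exceeds 64 characters")
  uid
}

#' Validate DICOM UID syntax
#'
#' A UID is valid if it is a non-empty dotted-decimal string of at most 64
#' characters whose components have no leading zeros (single "0" allowed).
#'
#' @param uid character scalar.
#' @return logical scalar.
#' @export
is_valid_uid <- function(uid) {
  if (!is.character(uid) || length(uid) != 1L || is.na(uid)) return(FALSE)
  if (nchar(uid) < 1L || nchar(uid) > 64L) return(FALSE)
  grepl("^(0|[1-9][0-9]*)(\\.(0|[1-9][0-9]*))+$", uid)
}
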