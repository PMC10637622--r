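#' Listener/router: series filtering, anonymization, timeout completion
#'
#' The router accepts inbound instances, keeps a per-series receive buffer,
#' and declares a series complete once no further instance has arrived for
#' \code{timeout_s} seconds (default 30 s). All time-dependent operations
#' take the current time as an argument, so tests drive a simulated clock and
#' a deployment wires a wall clock.
#'
#' @name qv-router
NULL

# ---- series filter ----------------------------------------------------------

#' Series-description filter
#'
#' @param patterns character vector of patterns. A description matches when
#'   any pattern occurs in it as a case-insensitive substring. An empty
#'   pattern list accepts nothing (fail-closed).
#' @return A \code{series_filter}.
#' @export
series_filter <- function(patterns = character(0)) {
  structure(list(patterns = as.character(patterns)), class = "series_filter")
}

#' Match a series description against a filter
#' @param description series description text.
#' @param filter a \code{series_filter}.
#' @return logical scalar.
#' @export
match_series <- function(description, filter) {
  if (length(filter$patterns) == 0L) return(FALSE)
  if (is.null(description) || length(description) == 0L) return(FALSE)
  desc <- tolower(description)
  any(vapply(tolower(filter$patterns), function(p)
    grepl(p, desc, fixed = TRUE), logical(1)))
}

# ---- anonymizer -------------------------------------------------------------

# de-identification list: a documented subset of the DICOM Basic Profile.
# "remove" drops the element; "replace" substitutes the placeholder; "empty"
# keeps the element with a zero-length value.
.qv_deid_actions <- list(
  PatientName = "replace",
  PatientID = "replace",
  PatientBirthDate = "empty",
  PatientSex = "empty",
  PatientAge = "remove",
  PatientAddress = "remove",
  PatientTelephoneNumbers = "remove",
  AccessionNumber = "empty",
  InstitutionName = "remove",
  InstitutionAddress = "remove",
  ReferringPhysicianName = "empty",
  PerformingPhysicianName = "remove",
  OperatorsName = "remove",
  DeviceSerialNumber = "remove",
  StudyID = "empty"
)

#' Identifying tags handled by the anonymizer
#' @return Character vector of DICOM keywords in the shipped
#'   de-identification list (private tags are removed in addition).
#' @export
deidentification_tags <- function() names(.qv_deid_actions)

#' Create an anonymization map
#'
#' Holds a memoized, injective original-to-replacement UID table. A UID
#' queried twice returns the same replacement; replacement UIDs map to
#' themselves, which makes anonymization idempotent.
#'
#' @param uid_root organizational root for replacement UIDs.
#' @param placeholder_name,placeholder_id values substituted for patient
#'   name / patient ID.
#' @return An \code{anonymization_map} (environment-backed, so shared across
#'   calls that receive it).
#' @export
anonymization_map <- function(uid_root = qv_default_uid_root(),
                              placeholder_name = "ANONYMOUS",
                              placeholder_id = "ANON") {
  e <- new.env(parent = emptyenv())
  e$uid_map <- new.env(parent = emptyenv())
  e$uid_root <- uid_root
  e$placeholder_name <- placeholder_name
  e$placeholder_id <- placeholder_id
  class(e) <- "anonymization_map"
  e
}

#' Look up (or mint) the replacement for a UID
#' @param map an \code{anonymization_map}.
#' @param uid original UID.
#' @return Replacement UID (stable across calls with the same map).
#' @export
map_uid <- function(map, uid) {
  hit <- get0(uid, envir = map$uid_map, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  repl <- new_uid(map$uid_root)
  assign(uid, repl, envir = map$uid_map)
  assign(repl, repl, envir = map$uid_map)  # idempotence: repl maps to itself
  repl
}

#' Anonymize a DICOM instance
#'
#' Applies the shipped de-identification list (see
#' \code{\link{deidentification_tags}}), removes all private (odd-group)
#' tags, remaps the study/series/SOP/frame-of-reference UIDs consistently via
#' the map, and records the de-identification method. Geometry tags, pixel
#' data, rescale tags and the series description pass through unchanged.
#'
#' @param instance a \code{dicom_dataset}.
#' @param map an \code{anonymization_map} shared across the study.
#' @return The anonymized \code{dicom_dataset}.
#' @export
anonymize <- function(instance, map) {
  ds <- instance
  for (nm in names(.qv_deid_actions)) {
    if (!dcm_has(ds, nm)) next
    action <- .qv_deid_actions[[nm]]
    if (action == "remove") {
      ds <- dcm_del(ds, nm)
    } else if (action == "empty") {
      ds <- dcm_set(ds, nm, character(0))
    } else {
      ds <- dcm_set(ds, nm,
                    if (nm == "PatientID") map$placeholder_id
                    else map$placeholder_name)
    }
  }
  # drop private tags (odd group numbers)
  for (key in names(ds$elements)) {
    group <- strtoi(substr(key, 1L, 4L), 16L)
    if (group %% 2L == 1L) ds$elements[[key]] <- NULL
  }
  for (nm in c("StudyInstanceUID", "SeriesInstanceUID", "SOPInstanceUID",
               "FrameOfReferenceUID")) {
    uid <- dcm_get(ds, nm)
    if (!is.null(uid)) ds <- dcm_set(ds, nm, map_uid(map, uid))
  }
  ds <- dcm_set(ds, "PatientIdentityRemoved", "YES")
  ds <- dcm_set(ds, "DeidentificationMethod",
                "qvbridge basic-profile subset; UID remap")
  ds
}

# ---- timeout state machine --------------------------------------------------

#' Create router state
#'
#' @param timeout_s series-completion timeout in seconds. The shipped default
#'   is 30 s: a series is considered complete once no further instance has
#'   arrived for this long.
#' @return A \code{router_state} with empty buffers and queue.
#' @export
router_state <- function(timeout_s = 30) {
  if (!is.numeric(timeout_s) || timeout_s <= 0)
    qv_stop("qv_validation_error", "timeout_s must be positive",
            field = "timeout_s")
  structure(list(buffers = list(), queue = list(), timeout_s = timeout_s),
            class = "router_state")
}

#' Receive one instance into the router
#'
#' Stores the instance in its series buffer (creating the buffer if absent),
#' resets the buffer's deadline to \code{now + timeout_s}, and silently
#' replaces an already-buffered SOP instance (retransmission is normal DICOM
#' behaviour). Instances with a missing or invalid UID triple are rejected
#' without changing any buffer.
#'
#' @param state a \code{router_state}.
#' @param instance a \code{dicom_dataset} that already passed the series
#'   filter.
#' @param now current time in seconds (simulated or wall clock).
#' @return The updated \code{router_state}.
#' @export
on_instance_received <- function(state, instance, now) {
  dcm_validate_uids(instance)
  series_uid <- dcm_get(instance, "SeriesInstanceUID")
  sop_uid <- dcm_get(instance, "SOPInstanceUID")
  buf <- state$buffers[[series_uid]]
  if (is.null(buf))
    buf <- list(instances = list(), last_receipt_time = NA_real_,
                deadline = NA_real_)
  buf$instances[[sop_uid]] <- instance
  buf$last_receipt_time <- now
  buf$deadline <- now + state$timeout_s
  state$buffers[[series_uid]] <- buf
  state
}

#' Collect series whose timeout has elapsed
#'
#' Every live buffer with \code{now >= deadline} (boundary inclusive) is
#' moved from the buffers to the processing queue, in deadline order.
#'
#' @param state a \code{router_state}.
#' @param now current time in seconds.
#' @return list with \code{state} (updated) and \code{completed}: a list of
#'   \code{list(series_uid, instances)} newly completed, in completion order.
#' @export
poll_completions <- function(state, now) {
  if (length(state$buffers) == 0L)
    return(list(state = state, completed = list()))
  deadlines <- vapply(state$buffers, function(b) b$deadline, numeric(1))
  due <- names(deadlines)[now >= deadlines]
  due <- due[order(deadlines[due])]
  completed <- lapply(due, function(uid) {
    list(series_uid = uid,
         instances = unname(state$buffers[[uid]]$instances))
  })
  names(completed) <- NULL
  state$buffers[due] <- NULL
  state$queue <- c(state$queue, completed)
  list(state = state, completed = completed)
}

# ---- delivery sinks ---------------------------------------------------------

#' Directory delivery sink
#'
#' A sink receives DICOM instances via \code{\link{deliver}}. The directory
#' sink writes one part-10 file per instance, named by SOP instance UID —
#' the hermetic stand-in for a networked store destination.
#'
#' @param dir target directory (created if needed).
#' @param name sink name used in receipts and error messages.
#' @return A \code{qv_sink}.
#' @export
dir_sink <- function(dir, name = basename(dir)) {
  structure(list(kind = "dir", dir = dir, name = name),
            class = c("qv_dir_sink", "qv_sink"))
}

#' Function delivery sink
#'
#' Wraps an arbitrary function \code{fn(instance)} as a sink; used for
#' in-memory collection and fault injection in tests, and as the adapter
#' point for a networked store client.
#'
#' @param fn function called once per instance; any error counts as a
#'   delivery failure for that instance.
#' @param name sink name.
#' @return A \code{qv_sink}.
#' @export
function_sink <- function(fn, name = "function-sink") {
  structure(list(kind = "function", fn = fn, name = name),
            class = c("qv_function_sink", "qv_sink"))
}

deliver_one <- function(sink, instance) {
  if (inherits(sink, "qv_dir_sink")) {
    dir.create(sink$dir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(sink$dir,
                      paste0(dcm_get(instance, "SOPInstanceUID"), ".dcm"))
    write_dicom(instance, path)
  } else if (inherits(sink, "qv_function_sink")) {
    sink$fn(instance)
  } else {
    qv_stop("qv_validation_error", "unknown sink type")
  }
  invisible(TRUE)
}

#' Deliver instances to a sink, with retries
#'
#' @param sink a \code{qv_sink}.
#' @param instances list of \code{dicom_dataset}.
#' @param retries additional attempts per instance after the first failure.
#' @return Data frame receipt with columns \code{sop_instance_uid},
#'   \code{sink}, \code{ok}. Signals \code{qv_delivery_error} naming the sink
#'   and the undelivered SOP UIDs when any instance cannot be delivered.
#' @export
deliver <- function(sink, instances, retries = 2L) {
  ok <- logical(length(instances))
  sops <- vapply(instances, dcm_get, character(1), name = "SOPInstanceUID")
  for (i in seq_along(instances)) {
    for (attempt in seq_len(retries + 1L)) {
      ok[i] <- tryCatch({deliver_one(sink, instances[[i]]); TRUE},
                        error = function(e) FALSE)
      if (ok[i]) break
    }
  }
  if (!all(ok))
    qv_stop("qv_delivery_error",
            sprintf("sink '%s' failed to deliver %d instance(s): %s",
                    sink$name, sum(!ok),
                    paste(sops[!ok], collapse = ", ")),
            sink = sink$name, undelivered = sops[!ok])
  data.frame(sop_instance_uid = sops, sink = sink$name, ok = ok,
             stringsAsFactors = FALSE)
}

#' Dispatch a completed series to the archive and processing sinks
#'
#' @param series a completed series (\code{list(series_uid, instances)}) as
#'   returned by \code{\link{poll_completions}}.
#' @param archive_sink,processing_sink \code{qv_sink}s receiving every
#'   instance.
#' @param retries per-instance retry count passed to \code{\link{deliver}}.
#' @return list of per-sink receipts.
#' @export
dispatch <- function(series, archive_sink, processing_sink, retries = 2L) {
  list(archive = deliver(archive_sink, series$instances, retries = retries),
       processing = deliver(processing_sink, series$instances,
                            retries = retries))
}
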