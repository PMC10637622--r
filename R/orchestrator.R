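#' One-command end-to-end pipeline
#'
#' Wires router -> volume assembly -> segmenter -> SEG codec -> volumetry/SR
#' in a single process with directory transport: an inbox directory stands in
#' for the inbound store service and an archive directory for the
#' query/retrieve archive, so a networked two-host deployment is a transport
#' change, not a code change. Completed series are processed strictly one at
#' a time in completion order.
#'
#' @name qv-orchestrator
NULL

#' Pipeline configuration
#'
#' @param inbox_dir directory watched for inbound part-10 files.
#' @param archive_dir directory receiving the anonymized series, SEG and SR.
#' @param work_dir scratch root; each series gets a unique subdirectory.
#' @param series_filters character vector of case-insensitive substring
#'   patterns a series description must match to be accepted.
#' @param timeout_s series-completion timeout in seconds (default 30).
#' @param segmenter list(name, params) naming a plugin known to
#'   \code{\link{make_plugin}}.
#' @param segment_metadata path to the segment-metadata JSON, or a
#'   \code{segment_descriptor}.
#' @param uid_root organizational UID root for minted UIDs.
#' @param retries delivery retries per instance.
#' @param verbose emit per-stage log messages.
#' @return A validated \code{pipeline_config}.
#' @export
pipeline_config <- function(inbox_dir, archive_dir, work_dir = tempfile("qv_work_"),
                            series_filters = c("portal venous"),
                            timeout_s = 30,
                            segmenter = list(name = "reference_threshold",
                                             params = list(hu_low = 40, hu_high = 80)),
                            segment_metadata = NULL,
                            uid_root = qv_default_uid_root(),
                            retries = 2L, verbose = FALSE) {
  if (!is.numeric(timeout_s) || timeout_s <= 0)
    qv_stop("qv_validation_error", "timeout_s must be positive",
            field = "timeout_s")
  if (!dir.exists(inbox_dir))
    qv_stop("qv_validation_error",
            sprintf("inbox directory does not exist: %s", inbox_dir),
            field = "inbox_dir")
  desc <- if (inherits(segment_metadata, "segment_descriptor")) {
    segment_metadata
  } else if (is.character(segment_metadata)) {
    load_segment_metadata(segment_metadata)
  } else if (is.null(segment_metadata)) {
    segment_descriptor("lesion")
  } else {
    qv_stop("qv_validation_error",
            "segment_metadata must be a path or a segment_descriptor")
  }
  structure(list(inbox_dir = inbox_dir, archive_dir = archive_dir,
                 work_dir = work_dir,
                 series_filters = series_filters, timeout_s = timeout_s,
                 segmenter = segmenter, descriptor = desc,
                 uid_root = uid_root, retries = as.integer(retries),
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Read a pipeline config from YAML
#'
#' Recognized keys: \code{inbox_dir}, \code{archive_dir}, \code{work_dir},
#' \code{series_filters}, \code{timeout_s}, \code{segmenter} (\code{name} +
#' \code{params}), \code{segment_metadata}, \code{uid_root}, \code{retries}.
#'
#' @param path YAML file path.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    qv_stop("qv_parse_error", sprintf("no such config file: %s", path))
  y <- tryCatch(yaml::read_yaml(path), error = function(e)
    qv_stop("qv_parse_error", sprintf("malformed YAML config %s: %s", path,
                                      conditionMessage(e))))
  args <- y[intersect(names(y), c("inbox_dir", "archive_dir", "work_dir",
                                  "series_filters", "timeout_s", "segmenter",
                                  "segment_metadata", "uid_root", "retries",
                                  "verbose"))]
  args$series_filters <- unlist(args$series_filters)
  do.call(pipeline_config, args)
}

qv_log <- function(config, fmt, ...) {
  if (isTRUE(config$verbose)) message(sprintf(paste0("[qvbridge] ", fmt), ...))
}

# process one completed (already anonymized) series; returns a summary row
qv_process_series <- function(series, config, archive_sink, plugin) {
  t0 <- proc.time()[["elapsed"]]
  timing <- list()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timing[[stage]] <<- t1 - t0
    t0 <<- t1
  }
  deliver(archive_sink, series$instances, retries = config$retries)
  tick("archive_s")

  vol <- assemble_volume(series$instances)
  workdir <- file.path(config$work_dir, series$series_uid)
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  write_volume(vol, file.path(workdir, "image.nii.gz"))
  tick("convert_s")

  mask <- run_plugin(plugin, vol)
  tick("inference_s")

  study_uid <- dcm_get(series$instances[[1L]], "StudyInstanceUID")
  if (all(mask$voxels == 0)) {
    # documented policy: no SEG for an empty result, but a zero-volume SR
    sr <- build_sr(0, config$descriptor, study_uid, series$series_uid,
                   uid_root = config$uid_root)
    deliver(archive_sink, list(sr$dataset), retries = config$retries)
    tick("report_s")
    return(list(status = "empty-result", volume_ml = 0,
                statement = sr$statement, timing = timing,
                sr_sop_uid = sr$sop_instance_uid, seg_sop_uid = NA_character_))
  }

  seg <- encode_seg(mask, series$instances, config$descriptor,
                    uid_root = config$uid_root)
  write_volume(mask, file.path(workdir, "labels.nii.gz"))
  write_dicom(seg, file.path(workdir, "seg.dcm"))
  tick("encode_s")

  # fail-fast re-validation of the returned SEG against the routed series
  validate_seg_linkage(seg, series$instances)
  v_seg <- seg_volume_ml(seg, series$instances)
  v_mask <- nifti_volume_ml(mask)
  if (abs(v_seg - v_mask) > 0.1)
    qv_stop("qv_validation_error",
            sprintf("SEG/label volume disagreement: %.3f vs %.3f mL",
                    v_seg, v_mask))
  sr <- build_sr(v_seg, config$descriptor, study_uid, series$series_uid,
                 seg_sop_uid = dcm_get(seg, "SOPInstanceUID"),
                 seg_series_uid = dcm_get(seg, "SeriesInstanceUID"),
                 uid_root = config$uid_root)
  deliver(archive_sink, list(seg), retries = config$retries)
  deliver(archive_sink, list(sr$dataset), retries = config$retries)
  tick("report_s")
  list(status = "ok", volume_ml = v_seg, statement = sr$statement,
       timing = timing, sr_sop_uid = sr$sop_instance_uid,
       seg_sop_uid = dcm_get(seg, "SOPInstanceUID"))
}

#' Run the pipeline over an inbox of DICOM files
#'
#' Reads every part-10 file in the inbox, filters by series description,
#' anonymizes with a study-consistent UID map, detects series completion
#' with the simulated-receipt timeout, and for each completed series (in
#' completion order, one at a time): delivers the anonymized series to the
#' archive, assembles the volume, runs the segmenter plugin, encodes and
#' delivers the SEG, computes the volume from SEG pixel data, and delivers
#' the SR. A failing series is marked failed in the summary and the
#' pipeline continues with the next one.
#'
#' @param config a \code{pipeline_config}.
#' @return A data frame: one row per processed series with status,
#'   volume_ml, statement, instance count and per-stage timings (seconds).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  filt <- series_filter(config$series_filters)
  anon <- anonymization_map(uid_root = config$uid_root)
  plugin <- make_plugin(config$segmenter$name,
                        config$segmenter$params %||% list())
  archive_sink <- dir_sink(config$archive_dir, name = "archive")

  instances <- read_dicom_dir(config$inbox_dir)
  state <- router_state(timeout_s = config$timeout_s)
  now <- 0
  for (inst in instances) {
    if (!match_series(dcm_get(inst, "SeriesDescription", ""), filt)) next
    state <- on_instance_received(state, anonymize(inst, anon), now)
  }
  res <- poll_completions(state, now + config$timeout_s)
  completed <- res$completed
  qv_log(config, "%d series completed from %d inbound file(s)",
         length(completed), length(instances))

  rows <- lapply(completed, function(series) {
    out <- tryCatch(
      qv_process_series(series, config, archive_sink, plugin),
      qv_error = function(e) list(status = "failed",
                                  volume_ml = NA_real_,
                                  statement = conditionMessage(e),
                                  timing = list(),
                                  sr_sop_uid = NA_character_,
                                  seg_sop_uid = NA_character_))
    qv_log(config, "series %s: %s (%s)", series$series_uid, out$status,
           out$statement)
    data.frame(series_uid = series$series_uid,
               n_instances = length(series$instances),
               status = out$status,
               volume_ml = out$volume_ml,
               statement = out$statement,
               seg_sop_uid = out$seg_sop_uid,
               sr_sop_uid = out$sr_sop_uid,
               archive_s = out$timing[["archive_s"]] %||% NA_real_,
               convert_s = out$timing[["convert_s"]] %||% NA_real_,
               inference_s = out$timing[["inference_s"]] %||% NA_real_,
               encode_s = out$timing[["encode_s"]] %||% NA_real_,
               report_s = out$timing[["report_s"]] %||% NA_real_,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    return(data.frame(series_uid = character(0), n_instances = integer(0),
                      status = character(0), volume_ml = numeric(0),
                      statement = character(0), seg_sop_uid = character(0),
                      sr_sop_uid = character(0), archive_s = numeric(0),
                      convert_s = numeric(0), inference_s = numeric(0),
                      encode_s = numeric(0), report_s = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hermetic end-to-end demonstration
#'
#' Generates a phantom study (one portal-venous series with a known-volume
#' ellipsoidal lesion plus one non-matching "Scout" series), runs the full
#' pipeline through directory transport, and reports the SR volume next to
#' the phantom's voxelized ground-truth volume. Reproducible for a fixed
#' seed (UIDs aside).
#'
#' @param seed integer seed.
#' @param out_dir output root; inbox/, archive/ and work/ are created
#'   beneath it.
#' @param n_slices number of slices in the matching series.
#' @return list with the run \code{summary} data frame, the SR
#'   \code{statement}, \code{sr_volume_ml}, \code{expected_volume_ml}
#'   (voxelized oracle), and \code{analytic_volume_ml}.
#' @export
demo_pipeline <- function(seed = 1L, out_dir = tempfile("qv_demo_"),
                          n_slices = 40L) {
  set.seed(seed)
  inbox <- file.path(out_dir, "inbox")
  archive <- file.path(out_dir, "archive")
  work <- file.path(out_dir, "work")
  for (d in c(inbox, archive, work))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)

  lesion <- ellipsoid_lesion(c(-74.4, -55.2, 50 + 1.5 * n_slices),
                             radii_mm = c(16, 12, 20), hu = 60,
                             label_value = 1L)
  spec <- phantom_spec(rows = 64L, cols = 64L, n_slices = n_slices,
                       lesions = list(lesion), seed = seed)
  scout <- phantom_spec(rows = 32L, cols = 32L, n_slices = 3L,
                        series_description = "Scout",
                        seed = seed + 1L)
  write_series(generate_ct_series(spec), inbox)
  write_series(generate_ct_series(scout), inbox)

  config <- pipeline_config(
    inbox_dir = inbox, archive_dir = archive, work_dir = work,
    series_filters = c("portal venous"),
    segment_metadata = segment_descriptor("hemorrhage",
                                          rgb = c(255L, 0L, 0L)))
  summary <- run_pipeline(config)
  expected <- nifti_volume_ml(ground_truth_mask(spec))
  list(summary = summary,
       statement = summary$statement[summary$status == "ok"][1L],
       sr_volume_ml = summary$volume_ml[summary$status == "ok"][1L],
       expected_volume_ml = expected,
       analytic_volume_ml = analytic_volume_ml(lesion),
       archive_dir = archive)
}

#' Validate the UID tree of an archive directory
#'
#' Walks every DICOM file delivered to an archive and confirms: a single
#' study UID; every SEG frame reference resolves to an archived image;
#' every SR evidence reference (study, series, SEG instance) resolves; and
#' no identifying tag from the de-identification list survives anywhere.
#'
#' @param dir archive directory.
#' @return list with \code{ok} (logical), \code{problems} (character
#'   vector), and instance counts per modality.
#' @export
validate_archive <- function(dir) {
  files <- read_dicom_dir(dir)
  problems <- character(0)
  if (length(files) == 0L)
    return(list(ok = FALSE, problems = "archive is empty",
                n_images = 0L, n_seg = 0L, n_sr = 0L))
  modality <- vapply(files, function(d) dcm_get(d, "Modality", ""), character(1))
  images <- files[modality == "CT"]
  segs <- files[modality == "SEG"]
  srs <- files[modality == "SR"]

  studies <- unique(vapply(files, dcm_get, character(1),
                           name = "StudyInstanceUID"))
  if (length(studies) != 1L)
    problems <- c(problems, sprintf("expected one study UID, found %d",
                                    length(studies)))
  img_sops <- vapply(images, dcm_get, character(1), name = "SOPInstanceUID")
  series_uids <- unique(c(
    vapply(files, dcm_get, character(1), name = "SeriesInstanceUID")))

  for (seg in segs) {
    refs <- tryCatch(seg_frame_references(seg), qv_error = function(e) {
      problems <<- c(problems, conditionMessage(e))
      character(0)
    })
    missing <- setdiff(refs, img_sops)
    if (length(missing))
      problems <- c(problems,
                    sprintf("SEG %s: unresolved frame reference(s) %s",
                            dcm_get(seg, "SOPInstanceUID"),
                            paste(missing, collapse = ", ")))
  }
  seg_sops <- vapply(segs, dcm_get, character(1), name = "SOPInstanceUID")
  for (sr in srs) {
    ev <- dcm_get(sr, "CurrentRequestedProcedureEvidenceSequence")
    if (is.null(ev)) {
      problems <- c(problems, "SR without evidence references")
      next
    }
    for (study_item in ev) {
      if (!identical(dcm_get(study_item, "StudyInstanceUID"), studies[1L]))
        problems <- c(problems, "SR references a foreign study UID")
      for (ser in dcm_get(study_item, "ReferencedSeriesSequence") %||% list()) {
        if (!dcm_get(ser, "SeriesInstanceUID") %in% series_uids)
          problems <- c(problems, "SR references an unknown series UID")
        for (ri in dcm_get(ser, "ReferencedInstanceSequence") %||% list()) {
          sop <- dcm_get(ri, "ReferencedSOPInstanceUID")
          if (!sop %in% c(img_sops, seg_sops))
            problems <- c(problems,
                          sprintf("SR references unknown instance %s", sop))
        }
      }
    }
  }
  # anonymization scan: no identifying value may survive
  for (f in names(files)) {
    ds <- files[[f]]
    for (nm in deidentification_tags()) {
      action <- .qv_deid_actions[[nm]]
      val <- dcm_get(ds, nm)
      if (action == "remove" && !is.null(val))
        problems <- c(problems, sprintf("%s: identifying tag %s present", f, nm))
      if (action %in% c("empty", "replace") && length(val) &&
          nm %in% c("PatientBirthDate", "AccessionNumber") && nzchar(val[1L]))
        problems <- c(problems, sprintf("%s: identifying tag %s not cleared", f, nm))
    }
    for (key in names(ds$elements)) {
      if (strtoi(substr(key, 1L, 4L), 16L) %% 2L == 1L)
        problems <- c(problems, sprintf("%s: private tag %s present", f, key))
    }
  }
  list(ok = length(problems) == 0L, problems = problems,
       n_images = length(images), n_seg = length(segs), n_sr = length(srs))
}
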