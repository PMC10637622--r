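# End-to-end orchestration: conservation, linkage, policies, containment.

demo_small <- function(seed = 3L) {
  # session tempdir: cleaned up when the test process exits
  demo_pipeline(seed = seed, out_dir = tempfile("qvdemo_"), n_slices = 16L)
}

test_that("the hermetic demo delivers series + SEG + SR under one study UID", {
  res <- demo_small()
  expect_identical(res$summary$status[res$summary$status != "failed"], "ok")
  v <- validate_archive(res$archive_dir)
  expect_true(v$ok)
  expect_identical(v$n_images, 16L)    # scout series filtered out
  expect_identical(v$n_seg, 1L)
  expect_identical(v$n_sr, 1L)
  files <- read_dicom_dir(res$archive_dir)
  expect_length(unique(vapply(files, dcm_get, character(1),
                              name = "StudyInstanceUID")), 1L)
  # SR volume equals the phantom voxelized oracle exactly
  expect_equal(res$sr_volume_ml, res$expected_volume_ml, tolerance = 1e-9)
  expect_match(res$statement, "^hemorrhage volume: ")
})

test_that("a non-matching series never reaches the archive or the summary", {
  res <- demo_small(seed = 11L)
  expect_identical(nrow(res$summary), 1L)
  descs <- vapply(read_dicom_dir(res$archive_dir), function(d)
    dcm_get(d, "SeriesDescription", ""), character(1))
  expect_false(any(grepl("scout", descs, ignore.case = TRUE)))
})

test_that("an empty segmentation yields a zero-volume SR and no SEG", {
  out_dir <- withr::local_tempdir()
  inbox <- file.path(out_dir, "inbox"); dir.create(inbox)
  spec <- tiny_spec(rows = 12L, cols = 12L, n_slices = 5L, hu = 700)
  write_series(generate_ct_series(spec), inbox)
  config <- pipeline_config(
    inbox_dir = inbox, archive_dir = file.path(out_dir, "archive"),
    work_dir = file.path(out_dir, "work"),
    segmenter = list(name = "reference_threshold",
                     params = list(hu_low = 40, hu_high = 80)))
  summary <- run_pipeline(config)
  expect_identical(summary$status, "empty-result")
  expect_identical(summary$volume_ml, 0)
  v <- validate_archive(file.path(out_dir, "archive"))
  expect_identical(v$n_seg, 0L)
  expect_identical(v$n_sr, 1L)
  expect_true(v$ok)
})

test_that("one failing series leaves its neighbors fully delivered", {
  out_dir <- withr::local_tempdir()
  inbox <- file.path(out_dir, "inbox"); dir.create(inbox)
  # three series; the middle one is marked by its distinctive slice count
  for (k in 1:3)
    write_series(generate_ct_series(
      tiny_spec(rows = 12L, cols = 12L,
                n_slices = if (k == 2L) 7L else 5L, seed = 100L + k)), inbox)

  booby_trapped <- local({
    base <- make_plugin("reference_threshold",
                        list(hu_low = 40, hu_high = 80))
    function(v) {
      if (dim(v$voxels)[3] == 7L) stop("injected failure")
      base$run(v)
    }
  })
  config <- pipeline_config(
    inbox_dir = inbox, archive_dir = file.path(out_dir, "archive"),
    work_dir = file.path(out_dir, "work"))
  # wire the failing plugin through the documented registry seam
  config$segmenter <- list(name = "reference_threshold", params = list())
  summary <- with_mocked_bindings(
    run_pipeline(config),
    make_plugin = function(name, params)
      segmenter_plugin("booby", booby_trapped))
  expect_identical(sum(summary$status == "failed"), 1L)
  expect_identical(sum(summary$status == "ok"), 2L)
  expect_identical(summary$n_instances[summary$status == "failed"], 7L)
  ok_uids <- summary$series_uid[summary$status == "ok"]
  archived <- read_dicom_dir(file.path(out_dir, "archive"))
  archived_series <- vapply(archived, dcm_get, character(1),
                            name = "SeriesInstanceUID")
  for (uid in ok_uids)
    expect_identical(sum(archived_series == uid), 5L)
})

test_that("pipeline config reads from YAML and validates", {
  out_dir <- withr::local_tempdir()
  inbox <- file.path(out_dir, "inbox"); dir.create(inbox)
  cfg_path <- file.path(out_dir, "config.yaml")
  writeLines(sprintf(
    "inbox_dir: %s\narchive_dir: %s\nseries_filters: [portal venous]\ntimeout_s: 30\nsegmenter:\n  name: reference_threshold\n  params:\n    hu_low: 40\n    hu_high: 80\n",
    inbox, file.path(out_dir, "archive")), cfg_path)
  config <- read_pipeline_config(cfg_path)
  expect_s3_class(config, "pipeline_config")
  expect_equal(config$timeout_s, 30)
  expect_identical(config$series_filters, "portal venous")

  writeLines("inbox_dir: /nonexistent-qv\narchive_dir: x", cfg_path)
  expect_error(read_pipeline_config(cfg_path), class = "qv_validation_error")
})

test_that("the archive validator catches broken linkage and identity leaks", {
  res <- demo_small(seed = 21L)
  archive <- res$archive_dir
  # remove one image file: SEG frame references must stop resolving
  files <- list.files(archive, pattern = "\\.dcm$", full.names = TRUE)
  segs <- files[vapply(files, function(f)
    identical(dcm_get(read_dicom(f), "Modality"), "SEG"), logical(1))]
  seg_refs <- seg_frame_references(read_dicom(segs[1L]))
  victim <- file.path(archive, paste0(seg_refs[1L], ".dcm"))
  file.remove(victim)
  v <- validate_archive(archive)
  expect_false(v$ok)
  expect_true(any(grepl("unresolved frame reference", v$problems)))

  # re-inject an identifying tag: the anonymization scan must flag it
  res2 <- demo_small(seed = 22L)
  files2 <- list.files(res2$archive_dir, pattern = "\\.dcm$",
                       full.names = TRUE)
  ds <- read_dicom(files2[1L])
  ds <- dcm_set(ds, "InstitutionName", "Leaky Hospital")
  write_dicom(ds, files2[1L])
  v2 <- validate_archive(res2$archive_dir)
  expect_false(v2$ok)
  expect_true(any(grepl("InstitutionName", v2$problems)))
})
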