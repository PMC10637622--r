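# Phantom generator: geometry tags, determinism, rasterization oracle,
# analytic volumes, and spec validation.

test_that("generated series carries the requested acquisition geometry", {
  spec <- phantom_spec(rows = 16L, cols = 16L, n_slices = 120L,
                      slice_thickness_mm = 3.0)
  series <- generate_ct_series(spec)
  expect_length(series, 120L)
  expect_identical(unique(vapply(series, dcm_get, numeric(1),
                                 name = "SliceThickness")), 3.0)
  study <- unique(vapply(series, dcm_get, character(1),
                         name = "StudyInstanceUID"))
  ser <- unique(vapply(series, dcm_get, character(1),
                       name = "SeriesInstanceUID"))
  sops <- vapply(series, dcm_get, character(1), name = "SOPInstanceUID")
  expect_length(study, 1L)
  expect_length(ser, 1L)
  expect_false(anyDuplicated(sops) > 0L)
  # positions advance along the slice normal in slice_spacing steps
  z <- vapply(series, function(x) dcm_get(x, "ImagePositionPatient")[3],
              numeric(1))
  expect_equal(diff(z), rep(3.0, 119L))
  expect_identical(dcm_get(series[[1L]], "SeriesDescription"),
                   spec$series_description)
})

test_that("a lesion-free phantom is uniform background after rescale", {
  spec <- phantom_spec(rows = 12L, cols = 12L, n_slices = 4L,
                       background_hu = -37)
  for (inst in generate_ct_series(spec))
    expect_true(all(dcm_hu_matrix(inst) == -37))
})

test_that("generation is deterministic for a fixed spec and seed", {
  spec <- tiny_spec(rows = 12L, cols = 12L, n_slices = 4L, seed = 42L)
  a <- generate_ct_series(spec)
  b <- generate_ct_series(spec)
  for (i in seq_along(a)) {
    expect_identical(dcm_get(a[[i]], "PixelData"), dcm_get(b[[i]], "PixelData"))
    expect_identical(dcm_get(a[[i]], "PatientName"),
                     dcm_get(b[[i]], "PatientName"))
    expect_equal(dcm_get(a[[i]], "ImagePositionPatient"),
                 dcm_get(b[[i]], "ImagePositionPatient"))
    # UIDs are fresh on every call
    expect_false(identical(dcm_get(a[[i]], "SOPInstanceUID"),
                           dcm_get(b[[i]], "SOPInstanceUID")))
  }
})

test_that("voxel-center rasterization matches a brute-force inclusion loop", {
  spec <- sphere_spec(spacing = 1.0)
  # keep the brute-force loop tractable
  expect_lte(spec$rows, 32L)
  mask <- ground_truth_mask(spec)
  expect_identical(sum(mask$voxels > 0), brute_force_voxel_count(spec))
})

test_that("degenerate rasterization cases behave as defined", {
  spec <- phantom_spec(rows = 10L, cols = 10L, n_slices = 4L)
  expect_true(all(ground_truth_mask(spec)$voxels == 0L))
  # a lesion smaller than half the voxel pitch placed on a voxel center
  spec1 <- phantom_spec(rows = 10L, cols = 10L, n_slices = 4L,
                        pixel_spacing_mm = c(1, 1), slice_thickness_mm = 1,
                        origin_mm = c(0, 0, 0),
                        lesions = list(ellipsoid_lesion(c(4, 5, 2),
                                                        rep(0.4, 3))))
  expect_identical(sum(ground_truth_mask(spec1)$voxels), 1L)
})

test_that("analytic ellipsoid volume follows the closed form", {
  expect_equal(analytic_volume_ml(ellipsoid_lesion(c(0, 0, 0), c(10, 10, 10))),
               4 / 3 * pi * 1000 / 1000, tolerance = 1e-8)
  expect_equal(analytic_volume_ml(ellipsoid_lesion(c(0, 0, 0), c(10, 20, 30))),
               25.13274, tolerance = 1e-6)
  l1 <- ellipsoid_lesion(c(0, 0, 0), c(4, 5, 6))
  l2 <- ellipsoid_lesion(c(0, 0, 0), 2 * c(4, 5, 6))
  expect_equal(analytic_volume_ml(l2), 8 * analytic_volume_ml(l1))
})

test_that("voxelized volume converges to the analytic volume under refinement", {
  analytic <- analytic_volume_ml(ellipsoid_lesion(c(0, 0, 0), rep(10, 3)))
  errs <- vapply(c(2, 1, 0.5), function(sp) {
    m <- ground_truth_mask(sphere_spec(sp))
    abs(sum(m$voxels > 0) * sp^3 / 1000 - analytic)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("ground truth and assembled image volume share one grid", {
  spec <- tiny_spec(rows = 16L, cols = 16L, n_slices = 6L)
  gt <- ground_truth_mask(spec)
  vol <- assemble_volume(generate_ct_series(spec))
  expect_identical(dim(gt$voxels), dim(vol$voxels))
  expect_lt(max(abs(gt$affine - vol$affine)), 1e-6)
})

test_that("phantom instances survive a strict part-10 read-back", {
  spec <- tiny_spec(rows = 12L, cols = 12L, n_slices = 3L)
  dir <- withr::local_tempdir()
  write_series(generate_ct_series(spec), dir)
  back <- read_dicom_dir(dir)
  expect_length(back, 3L)
  for (inst in back) {
    expect_equal(dcm_get(inst, "PixelSpacing"), spec$pixel_spacing_mm)
    expect_equal(dcm_get(inst, "ImageOrientationPatient"), spec$orientation)
    expect_equal(dcm_get(inst, "SliceThickness"), spec$slice_thickness_mm)
  }
})

test_that("invalid phantom specs are rejected with the offending field", {
  expect_error(phantom_spec(n_slices = 0L), class = "qv_validation_error")
  expect_error(phantom_spec(pixel_spacing_mm = c(0, 1)),
               class = "qv_validation_error")
  expect_error(phantom_spec(orientation = c(1, 0, 0, 1, 0, 0)),
               class = "qv_validation_error")
  expect_error(ellipsoid_lesion(c(0, 0, 0), c(-1, 2, 3)),
               class = "qv_validation_error")
  expect_error(phantom_spec(lesions = list(
    ellipsoid_lesion(c(0, 0, 0), c(1, 1, 1), label_value = 1L),
    ellipsoid_lesion(c(5, 5, 5), c(1, 1, 1), label_value = 1L))),
    class = "qv_validation_error")
  err <- tryCatch(phantom_spec(slice_thickness_mm = -3), qv_error = identity)
  expect_identical(err$field, "slice_thickness_mm")
})
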