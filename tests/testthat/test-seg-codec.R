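# SEG encode/decode, segment metadata, color coding, bit packing.

test_that("segment metadata file loads with defaults and strict validation", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"label": "hemorrhage", "rgb": [255, 0, 0]}', f)
  desc <- load_segment_metadata(f)
  expect_identical(desc$label, "hemorrhage")
  expect_identical(desc$rgb, c(255L, 0L, 0L))
  expect_identical(desc$segment_number, 1L)
  expect_true(all(c("scheme", "value", "meaning") %in%
                  names(desc$coded_type)))

  writeLines('{"label": "x", "rgb": [300, 0, 0]}', f)
  expect_error(load_segment_metadata(f), class = "qv_validation_error")
  writeLines('{"label": "x", "colour": [1, 2, 3]}', f)
  expect_error(load_segment_metadata(f), class = "qv_validation_error")
  writeLines('{"label": "x", "rgb": [1, 2, 3', f)
  expect_error(load_segment_metadata(f), class = "qv_parse_error")

  shipped <- system.file("extdata", "segment_metadata_example.json",
                         package = "qvbridge")
  desc2 <- load_segment_metadata(shipped)
  expect_identical(desc2$label, "hemorrhage")
  expect_identical(desc2$coded_type$meaning, "Hemorrhage")
})

test_that("8-bit sRGB round-trips exactly through 16-bit CIELab", {
  corners <- list(c(0, 0, 0), c(255, 255, 255), c(255, 0, 0), c(0, 255, 0),
                  c(0, 0, 255), c(255, 255, 0), c(0, 255, 255),
                  c(255, 0, 255))
  for (rgb in corners)
    expect_identical(cielab16_to_rgb(rgb_to_cielab16(rgb)), as.integer(rgb))
  set.seed(4)
  for (i in 1:50) {
    rgb <- sample(0:255, 3, replace = TRUE)
    expect_identical(cielab16_to_rgb(rgb_to_cielab16(rgb)), as.integer(rgb))
  }
  expect_error(rgb_to_cielab16(c(300, 0, 0)), class = "qv_validation_error")
})

test_that("SEG frames cover exactly the nonzero slices with per-frame links", {
  spec <- tiny_spec()
  series <- generate_ct_series(spec)
  mask <- ground_truth_mask(spec)
  desc <- segment_descriptor("hemorrhage", rgb = c(255L, 0L, 0L))
  seg <- encode_seg(mask, series, desc)

  nonzero_slices <- which(apply(mask$voxels > 0, 3, any))
  expect_equal(as.integer(dcm_get(seg, "NumberOfFrames")),
               length(nonzero_slices))
  sorted <- sort_slices(series)$instances
  expect_identical(seg_frame_references(seg),
                   vapply(sorted[nonzero_slices], dcm_get, character(1),
                          name = "SOPInstanceUID"))
  expect_identical(dcm_get(seg, "StudyInstanceUID"),
                   dcm_get(series[[1L]], "StudyInstanceUID"))
  expect_false(dcm_get(seg, "SeriesInstanceUID") ==
               dcm_get(series[[1L]], "SeriesInstanceUID"))
  expect_identical(dcm_get(seg, "SegmentationType"), "BINARY")
  expect_no_error(validate_seg_linkage(seg, series))
})

test_that("descriptor label and display color read back verbatim", {
  spec <- tiny_spec(rows = 12L, cols = 12L, n_slices = 4L)
  series <- generate_ct_series(spec)
  mask <- ground_truth_mask(spec)
  desc <- segment_descriptor("hemorrhage", rgb = c(255L, 0L, 0L))
  f <- withr::local_tempfile(fileext = ".dcm")
  write_dicom(encode_seg(mask, series, desc), f)
  seg <- read_dicom(f)
  item <- dcm_get(seg, "SegmentSequence")[[1L]]
  expect_identical(dcm_get(item, "SegmentLabel"), "hemorrhage")
  expect_identical(cielab16_to_rgb(dcm_get(item,
                                           "RecommendedDisplayCIELabValue")),
                   c(255L, 0L, 0L))
  expect_equal(dcm_get(item, "SegmentNumber"), 1L)
})

test_that("decode-encode is the identity on randomized phantom masks", {
  for (i in 1:6) {
    spec <- random_spec(i)
    series <- generate_ct_series(spec)
    mask <- ground_truth_mask(spec)
    seg <- encode_seg(mask, series, segment_descriptor("lesion"))
    dec <- decode_seg(seg, series)
    expect_identical(dec$voxels,
                     array(as.integer(mask$voxels > 0), dim(mask$voxels)),
                     info = sprintf("phantom %d", i))
    expect_lt(max(abs(dec$affine - mask$affine)), 1e-6)
  }
})

test_that("frame bit unpacking matches an independent bit-by-bit loop", {
  spec <- tiny_spec(rows = 10L, cols = 10L, n_slices = 6L)
  series <- generate_ct_series(spec)
  seg <- encode_seg(ground_truth_mask(spec), series,
                    segment_descriptor("lesion"))
  packed <- dcm_get(seg, "PixelData")
  nbits <- as.integer(dcm_get(seg, "NumberOfFrames")) * 10L * 10L
  manual <- integer(nbits)
  for (b in seq_len(nbits)) {
    byte <- as.integer(packed[((b - 1L) %/% 8L) + 1L])
    manual[b] <- bitwAnd(bitwShiftR(byte, (b - 1L) %% 8L), 1L)
  }
  expect_identical(seg_unpack_bits(seg), manual)
})

test_that("codec errors: grid mismatch, empty mask, foreign references", {
  spec <- tiny_spec(rows = 12L, cols = 12L, n_slices = 4L)
  series <- generate_ct_series(spec)
  mask <- ground_truth_mask(spec)
  desc <- segment_descriptor("lesion")

  small <- geometric_volume(mask$voxels[, , 1:3], mask$affine)
  expect_error(encode_seg(small, series, desc), class = "qv_geometry_error")

  shifted <- geometric_volume(mask$voxels, mask$affine +
                                matrix(c(rep(0, 3), 1e-2, rep(0, 12)), 4, 4))
  expect_error(encode_seg(shifted, series, desc), class = "qv_geometry_error")

  empty <- geometric_volume(array(0L, dim(mask$voxels)), mask$affine)
  expect_error(encode_seg(empty, series, desc),
               class = "qv_empty_segmentation_error")

  seg <- encode_seg(mask, series, desc)
  other <- generate_ct_series(tiny_spec(rows = 12L, cols = 12L,
                                        n_slices = 4L, seed = 99L))
  expect_error(decode_seg(seg, other), class = "qv_linkage_error")
})
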