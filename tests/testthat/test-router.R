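# Router: series filtering, anonymization, timeout state machine, dispatch.

test_that("series filter matches case-insensitive substrings, fail-closed", {
  f <- series_filter(c("portal venous"))
  expect_true(match_series("CHEST ABD PEL Portal Venous 3.0mm", f))
  expect_false(match_series("Scout", f))
  expect_false(match_series("anything at all", series_filter(character(0))))
  expect_true(match_series("ARTERIAL 1mm", series_filter(c("portal", "arterial"))))
})

test_that("anonymization replaces identity, keeps geometry, remaps UIDs consistently", {
  spec <- tiny_spec(rows = 8L, cols = 8L, n_slices = 2L)
  series <- generate_ct_series(spec)
  map <- anonymization_map()
  out <- lapply(series, anonymize, map = map)

  expect_identical(dcm_get(out[[1L]], "PatientName"), "ANONYMOUS")
  expect_false(dcm_has(out[[1L]], "InstitutionName"))
  expect_false(dcm_has(out[[1L]], "OperatorsName"))
  expect_false(dcm_has(out[[1L]], "DeviceSerialNumber"))
  expect_length(dcm_get(out[[1L]], "PatientBirthDate"), 0L)
  expect_length(dcm_get(out[[1L]], "AccessionNumber"), 0L)
  expect_null(out[[1L]]$elements[["0009,0010"]])   # private tag dropped
  expect_identical(dcm_get(out[[1L]], "PatientIdentityRemoved"), "YES")

  # pass-through invariants
  expect_equal(dcm_get(out[[1L]], "ImagePositionPatient"),
               dcm_get(series[[1L]], "ImagePositionPatient"))
  expect_identical(dcm_get(out[[1L]], "PixelData"),
                   dcm_get(series[[1L]], "PixelData"))
  expect_identical(dcm_get(out[[1L]], "SeriesDescription"),
                   dcm_get(series[[1L]], "SeriesDescription"))

  # UID remap: consistent across instances, never the original
  old_study <- dcm_get(series[[1L]], "StudyInstanceUID")
  new_study <- vapply(out, dcm_get, character(1), name = "StudyInstanceUID")
  expect_length(unique(new_study), 1L)
  expect_false(new_study[1L] == old_study)
  expect_true(is_valid_uid(new_study[1L]))
})

test_that("anonymization is idempotent tag-for-tag", {
  spec <- tiny_spec(rows = 8L, cols = 8L, n_slices = 1L)
  inst <- generate_ct_series(spec)[[1L]]
  map <- anonymization_map()
  once <- anonymize(inst, map)
  twice <- anonymize(once, map)
  expect_identical(sort(dcm_tags(twice)), sort(dcm_tags(once)))
  for (key in dcm_tags(once))
    expect_identical(twice$elements[[key]], once$elements[[key]],
                     info = key)
})

test_that("no identifying tag survives anonymization", {
  spec <- tiny_spec(rows = 8L, cols = 8L, n_slices = 1L)
  out <- anonymize(generate_ct_series(spec)[[1L]], anonymization_map())
  removed <- c("PatientAge", "PatientAddress", "PatientTelephoneNumbers",
               "InstitutionName", "InstitutionAddress",
               "PerformingPhysicianName", "OperatorsName",
               "DeviceSerialNumber")
  for (nm in removed) expect_false(dcm_has(out, nm), info = nm)
  for (key in dcm_tags(out))
    expect_true(strtoi(substr(key, 1, 4), 16L) %% 2L == 0L, info = key)
})

test_that("receive buffers track deadlines, dedup and reject invalid UIDs", {
  spec <- tiny_spec(rows = 8L, cols = 8L, n_slices = 3L)
  series <- generate_ct_series(spec)
  st <- router_state(timeout_s = 30)

  st <- on_instance_received(st, series[[1L]], now = 0)
  uid <- dcm_get(series[[1L]], "SeriesInstanceUID")
  expect_length(st$buffers[[uid]]$instances, 1L)
  expect_equal(st$buffers[[uid]]$deadline, 30)

  st <- on_instance_received(st, series[[2L]], now = 12)
  expect_length(st$buffers[[uid]]$instances, 2L)
  expect_equal(st$buffers[[uid]]$deadline, 42)

  st <- on_instance_received(st, series[[2L]], now = 13)  # retransmission
  expect_length(st$buffers[[uid]]$instances, 2L)

  bad <- dcm_set(series[[3L]], "SOPInstanceUID", "not-a-uid")
  expect_error(on_instance_received(st, bad, now = 14),
               class = "qv_validation_error")
  expect_length(st$buffers[[uid]]$instances, 2L)
})

test_that("series complete at the inclusive timeout boundary, in deadline order", {
  specA <- tiny_spec(rows = 8L, cols = 8L, n_slices = 1L, seed = 1L)
  specB <- tiny_spec(rows = 8L, cols = 8L, n_slices = 1L, seed = 2L)
  a <- generate_ct_series(specA)[[1L]]
  b <- generate_ct_series(specB)[[1L]]

  st <- router_state(timeout_s = 30)
  st <- on_instance_received(st, a, now = 12)   # deadline 42
  st <- on_instance_received(st, b, now = 5)    # deadline 35

  r <- poll_completions(st, now = 41.9)
  expect_length(r$completed, 1L)                 # only the 35-deadline series
  expect_identical(r$completed[[1L]]$series_uid,
                   dcm_get(b, "SeriesInstanceUID"))

  r2 <- poll_completions(st, now = 42.0)         # boundary inclusive
  expect_length(r2$completed, 2L)
  expect_identical(vapply(r2$completed, `[[`, character(1), "series_uid"),
                   c(dcm_get(b, "SeriesInstanceUID"),
                     dcm_get(a, "SeriesInstanceUID")))
  expect_length(r2$state$buffers, 0L)
})

test_that("randomized schedules: timeout correctness and conservation", {
  timeout <- 30
  for (trial in 1:20) {
    set.seed(trial)
    n_series <- sample(1:3, 1)
    specs <- lapply(seq_len(n_series), function(k)
      tiny_spec(rows = 8L, cols = 8L, n_slices = sample(2:5, 1),
                seed = trial * 10L + k))
    all_series <- lapply(specs, generate_ct_series)

    # build a schedule with inter-arrival gaps < timeout within each series
    events <- do.call(rbind, lapply(seq_along(all_series), function(k) {
      gaps <- stats::runif(length(all_series[[k]]), 0, timeout - 0.5)
      data.frame(k = k, i = seq_along(all_series[[k]]),
                 t = cumsum(gaps) + stats::runif(1, 0, 20))
    }))
    events <- events[order(events$t), ]

    st <- router_state(timeout_s = timeout)
    last_arrival <- numeric(0)
    done <- list()
    for (row in seq_len(nrow(events))) {
      ev <- events[row, ]
      # poll before delivering: a completion is legal only once the series'
      # own final instance is older than the timeout
      r <- poll_completions(st, now = ev$t)
      for (cs in r$completed) {
        expect_gte(ev$t, last_arrival[[cs$series_uid]] + timeout)
        # exactness: the same state completes at last + timeout, not before
        probe <- last_arrival[[cs$series_uid]] + timeout
        expect_false(cs$series_uid %in% vapply(
          poll_completions(st, probe - 1e-6)$completed,
          `[[`, character(1), "series_uid"))
        expect_true(cs$series_uid %in% vapply(
          poll_completions(st, probe)$completed,
          `[[`, character(1), "series_uid"))
        done[[cs$series_uid]] <- cs
      }
      st <- r$state
      inst <- all_series[[ev$k]][[ev$i]]
      last_arrival[[dcm_get(inst, "SeriesInstanceUID")]] <- ev$t
      st <- on_instance_received(st, inst, now = ev$t)
    }
    for (uid in names(st$buffers)) {
      probe <- last_arrival[[uid]] + timeout
      expect_false(uid %in% vapply(
        poll_completions(st, probe - 1e-6)$completed,
        `[[`, character(1), "series_uid"))
      expect_true(uid %in% vapply(
        poll_completions(st, probe)$completed,
        `[[`, character(1), "series_uid"))
    }
    final <- poll_completions(st, max(unlist(last_arrival)) + timeout)
    for (cs in final$completed) done[[cs$series_uid]] <- cs
    expect_length(done, n_series)
    # conservation: every accepted instance in exactly one completed series
    got <- unlist(lapply(done, function(cs)
      vapply(cs$instances, dcm_get, character(1), name = "SOPInstanceUID")))
    want <- unlist(lapply(all_series, function(s)
      vapply(s, dcm_get, character(1), name = "SOPInstanceUID")))
    expect_setequal(got, want)
    expect_false(anyDuplicated(got) > 0L)
  }
})

test_that("dispatch delivers every instance to both sinks and reports failures", {
  spec <- tiny_spec(rows = 8L, cols = 8L, n_slices = 4L)
  series <- list(series_uid = "s",
                 instances = generate_ct_series(spec))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  receipts <- dispatch(series, dir_sink(d1), dir_sink(d2))
  expect_length(list.files(d1, pattern = "\\.dcm$"), 4L)
  expect_length(list.files(d2, pattern = "\\.dcm$"), 4L)
  expect_true(all(receipts$archive$ok))
  # identical (already-anonymized) payload lands in both sinks
  expect_identical(sort(list.files(d1)), sort(list.files(d2)))

  broken <- function_sink(function(inst) stop("unreachable"), name = "dl-host")
  err <- tryCatch(dispatch(series, dir_sink(withr::local_tempdir()), broken),
                  qv_delivery_error = identity)
  expect_s3_class(err, "qv_delivery_error")
  expect_match(conditionMessage(err), "dl-host")
  expect_length(err$undelivered, 4L)
})
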