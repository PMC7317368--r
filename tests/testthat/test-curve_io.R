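write_fixture_files <- function(dir, times, strains,
                                qrs = 40, pvc = 390, pv_open = 110,
                                subject = "S001", segment = "basal",
                                framerate = 75) {
  curve_path <- file.path(dir, "curve.csv")
  events_path <- file.path(dir, "events.json")
  utils::write.csv(data.frame(time_ms = times, strain_pct = strains),
                   curve_path, row.names = FALSE)
  jsonlite::write_json(
    list(subject_id = subject, segment = segment, qrs_onset_ms = qrs,
         pv_open_ms = pv_open, pv_close_ms = pvc, framerate_hz = framerate),
    events_path, auto_unbox = TRUE, digits = NA)
  list(curve = curve_path, events = events_path)
}

test_that("a well-formed curve file round-trips through read_curve", {
  dir <- withr::local_tempdir()
  times <- seq(0, 79) * 13.3
  strains <- sin(times / 150) * -15
  p <- write_fixture_files(dir, times, strains)
  rec <- read_curve(p$curve, p$events)
  expect_s3_class(rec, "curve_record")
  expect_length(rec$curve$times, 80)
  expect_equal(rec$curve$times, times)
  expect_equal(rec$curve$strains, strains)
  expect_equal(rec$events$qrs_onset_ms, 40)
  expect_equal(rec$curve$framerate_hz, 75)
})

test_that("validation failures raise distinct classed errors", {
  dir <- withr::local_tempdir()
  times <- seq(0, 500, by = 10)
  strains <- -times / 50

  # events beyond the curve span
  p <- write_fixture_files(dir, times, strains, pvc = 9000)
  expect_error(read_curve(p$curve, p$events), class = "rv_span_error")

  # duplicated timestamp
  p <- write_fixture_files(dir, c(0, 10, 10, 30, 40, 400, 500),
                           rep(-5, 7), pvc = 390)
  expect_error(read_curve(p$curve, p$events),
               class = "rv_monotonicity_error")

  # missing column
  utils::write.csv(data.frame(t = times, strain_pct = strains),
                   file.path(dir, "bad.csv"), row.names = FALSE)
  p <- write_fixture_files(dir, times, strains)
  expect_error(read_curve(file.path(dir, "bad.csv"), p$events),
               class = "rv_column_error")

  # non-numeric cells
  tab <- data.frame(time_ms = c("0", "ten", "20", "30"),
                    strain_pct = c(-1, -2, -3, -4))
  utils::write.csv(tab, file.path(dir, "nonnum.csv"), row.names = FALSE)
  expect_error(read_curve(file.path(dir, "nonnum.csv"), p$events),
               class = "rv_numeric_error")

  # events file missing a required key
  jsonlite::write_json(list(subject_id = "S001", segment = "basal",
                            qrs_onset_ms = 40),
                       file.path(dir, "incomplete.json"), auto_unbox = TRUE)
  expect_error(read_curve(p$curve, file.path(dir, "incomplete.json")),
               class = "rv_field_error")
})

test_that("constructor invariants reject degenerate inputs", {
  expect_error(strain_curve("s", "basal", c(0, 10), c(-1, -2)),
               class = "rv_length_error")
  expect_error(strain_curve("s", "septal", 0:4, rep(-1, 5)),
               class = "rv_field_error")
  expect_error(strain_curve("s", "basal", 0:4, c(-1, NA, -3, -4, -5)),
               class = "rv_numeric_error")
  expect_error(cardiac_events(qrs_onset_ms = 400, pv_close_ms = 100),
               class = "rv_event_order_error")
  expect_error(cardiac_events(qrs_onset_ms = 0, pv_close_ms = 100,
                              pv_open_ms = 150),
               class = "rv_event_order_error")
})

test_that("write_metrics produces one row per curve and round-trips", {
  dir <- withr::local_tempdir()
  spec <- synthetic_spec("II", onset_true_ms = 120, sps_true_pct = -17,
                         psi_true_pct = 18, prestretch_amp_pct = 3)
  rec <- generate_curve(spec, "S009", "mid")
  res <- analyze_curve(rec)
  out <- file.path(dir, "metrics.csv")
  tab <- write_metrics(list(list(record = rec, metrics = res$metrics,
                                 classification = res$classification)),
                       out)
  expect_equal(nrow(tab), 1L)
  back <- utils::read.csv(out, stringsAsFactors = FALSE)
  expect_equal(nrow(back), 1L)
  expect_equal(back$subject_id, "S009")
  expect_equal(back$onset_ms, round(res$metrics$onset_ms, 1))
  expect_equal(back$psi_pct, round(res$metrics$psi_pct, 2))
  expect_equal(back$points_total, res$classification$points_total)
  expect_equal(back$type, res$classification$pattern_type)

  # failed curves appear as error rows
  tab2 <- write_metrics(list(
    list(record = rec, metrics = res$metrics,
         classification = res$classification),
    list(record = rec, error = "boom")
  ), out)
  expect_equal(nrow(tab2), 2L)
  expect_equal(tab2$errors[2], "boom")
  expect_true(is.na(tab2$onset_ms[2]))

  expect_error(write_metrics(list(), out), class = "rv_length_error")
})

test_that("curve files written by write_cohort re-read to declared precision", {
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(n_subjects = 2, segments = 2, seed = 11,
                            noise_sd_pct = 0.1)
  write_cohort(cohort, dir)
  records <- read_manifest(file.path(dir, "manifest.json"))
  expect_length(records, 4L)
  for (i in seq_along(records)) {
    orig <- cohort$records[[i]]
    back <- records[[i]]
    expect_equal(back$curve$subject_id, orig$curve$subject_id)
    expect_lt(max(abs(back$curve$times - orig$curve$times)), 0.1)
    expect_lt(max(abs(back$curve$strains - orig$curve$strains)), 0.01)
  }
})
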