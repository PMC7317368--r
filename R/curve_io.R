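#' Construct a strain curve
#'
#' A strain curve is one myocardial segment's longitudinal strain time
#' series, with shortening negative (the universal convention in deformation
#' imaging). Times are absolute milliseconds from the start of the exported
#' cine loop; the QRS onset is carried separately as an annotation (see
#' [cardiac_events()]) and is *not* assumed to be `t = 0`.
#'
#' @param subject_id Subject identifier (character scalar).
#' @param segment RV free-wall segment, one of `"basal"`, `"mid"`,
#'   `"apical"`.
#' @param times Numeric vector of sample times in ms, strictly increasing,
#'   length >= 3.
#' @param strains Numeric vector of longitudinal strain in percent, same
#'   length as `times`; negative values denote shortening.
#' @param framerate_hz Optional acquisition framerate in Hz (> 0). When
#'   given, the native frame duration used for time-frame statistics is
#'   `1000 / framerate_hz` rather than the median sample interval.
#' @return An object of class `strain_curve`.
#' @seealso [cardiac_events()], [curve_record()], [read_curve()]
#' @export
strain_curve <- function(subject_id, segment, times, strains,
                         framerate_hz = NULL) {
  rv_assert(is.character(subject_id) && length(subject_id) == 1L,
            "rv_field_error", "subject_id must be a single character string")
  rv_assert(is.character(segment) && length(segment) == 1L &&
              segment %in% c("basal", "mid", "apical"),
            "rv_field_error",
            "segment must be one of 'basal', 'mid', 'apical'")
  rv_assert(is.numeric(times) && is.numeric(strains),
            "rv_numeric_error", "times and strains must be numeric")
  rv_assert(length(times) == length(strains) && length(times) >= 3L,
            "rv_length_error",
            "times and strains must have equal length >= 3")
  rv_assert(all(is.finite(times)), "rv_numeric_error",
            "times contain non-finite values")
  rv_assert(all(is.finite(strains)), "rv_numeric_error",
            "strains contain non-finite values")
  rv_assert(all(diff(times) > 0), "rv_monotonicity_error",
            "times must be strictly increasing")
  if (!is.null(framerate_hz)) {
    rv_assert(is_scalar_number(framerate_hz) && framerate_hz > 0,
              "rv_field_error", "framerate_hz must be a positive number")
  }
  structure(
    list(subject_id = subject_id, segment = segment,
         times = as.numeric(times), strains = as.numeric(strains),
         framerate_hz = framerate_hz),
    class = "strain_curve"
  )
}

#' Construct a cardiac event annotation
#'
#' Carries the timing landmarks anchoring the analysis windows: QRS-complex
#' onset (the electrical reference all onset-of-shortening times are
#' measured from) and pulmonary valve closure (PVC, the end of RV systole,
#' from RV outflow-tract Doppler). Pulmonary valve opening is optional and
#' kept only as metadata.
#'
#' @param qrs_onset_ms QRS-complex onset, ms (same clock as the curve).
#' @param pv_close_ms Pulmonary valve closure, ms; must exceed
#'   `qrs_onset_ms`.
#' @param pv_open_ms Optional pulmonary valve opening, ms; must precede
#'   `pv_close_ms`.
#' @return An object of class `cardiac_events`.
#' @export
cardiac_events <- function(qrs_onset_ms, pv_close_ms, pv_open_ms = NULL) {
  rv_assert(is_scalar_number(qrs_onset_ms), "rv_numeric_error",
            "qrs_onset_ms must be a finite number")
  rv_assert(is_scalar_number(pv_close_ms), "rv_numeric_error",
            "pv_close_ms must be a finite number")
  rv_assert(qrs_onset_ms < pv_close_ms, "rv_event_order_error",
            "qrs_onset_ms must precede pv_close_ms")
  if (!is.null(pv_open_ms)) {
    rv_assert(is_scalar_number(pv_open_ms), "rv_numeric_error",
              "pv_open_ms must be a finite number")
    rv_assert(pv_open_ms < pv_close_ms, "rv_event_order_error",
              "pv_open_ms must precede pv_close_ms")
  }
  structure(
    list(qrs_onset_ms = qrs_onset_ms, pv_open_ms = pv_open_ms,
         pv_close_ms = pv_close_ms),
    class = "cardiac_events"
  )
}

#' Bind a strain curve to its event annotation
#'
#' Validates that the QRS onset and pulmonary valve closure both fall within
#' the recorded time span of the curve, so downstream windowing is always
#' defined.
#'
#' @param curve A [strain_curve()].
#' @param events A [cardiac_events()].
#' @param source_path Provenance string (file the curve was read from).
#' @return An object of class `curve_record`.
#' @export
curve_record <- function(curve, events, source_path = "") {
  rv_assert(inherits(curve, "strain_curve"), "rv_field_error",
            "curve must be a strain_curve")
  rv_assert(inherits(events, "cardiac_events"), "rv_field_error",
            "events must be a cardiac_events")
  span <- range(curve$times)
  rv_assert(events$qrs_onset_ms >= span[1] && events$qrs_onset_ms <= span[2],
            "rv_span_error",
            sprintf("qrs_onset_ms (%.1f) lies outside the curve span [%.1f, %.1f]",
                    events$qrs_onset_ms, span[1], span[2]))
  rv_assert(events$pv_close_ms >= span[1] && events$pv_close_ms <= span[2],
            "rv_span_error",
            sprintf("pv_close_ms (%.1f) lies outside the curve span [%.1f, %.1f]",
                    events$pv_close_ms, span[1], span[2]))
  structure(
    list(curve = curve, events = events, source_path = source_path),
    class = "curve_record"
  )
}

#' Read an event annotation file
#'
#' Accepts a JSON or YAML object with keys `subject_id`, `segment`,
#' `qrs_onset_ms`, `pv_close_ms`, optional `pv_open_ms` and optional
#' `framerate_hz`. The format is chosen by file extension (`.json` vs
#' `.yaml`/`.yml`).
#'
#' @param path Path to the events file.
#' @return A list with the parsed fields; `pv_open_ms`/`framerate_hz` are
#'   `NULL` when absent.
#' @export
read_events <- function(path) {
  rv_assert(file.exists(path), "rv_io_error",
            sprintf("events file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  obj <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  for (key in c("subject_id", "segment", "qrs_onset_ms", "pv_close_ms")) {
    rv_assert(!is.null(obj[[key]]), "rv_field_error",
              sprintf("events file %s is missing required key '%s'", path, key))
  }
  for (key in c("qrs_onset_ms", "pv_close_ms", "pv_open_ms", "framerate_hz")) {
    if (!is.null(obj[[key]])) {
      rv_assert(is_scalar_number(obj[[key]]), "rv_numeric_error",
                sprintf("events key '%s' in %s is not numeric", key, path))
    }
  }
  obj
}

#' Read one strain curve and its event annotation
#'
#' The curve file is two-column delimited text (comma separated, decimal
#' point) with header `time_ms,strain_pct`. Timestamps are preserved exactly
#' as read; all validation (column presence, numeric cells, strict time
#' monotonicity, events inside the curve span) raises a classed error naming
#' the offending field.
#'
#' @param path Path to the curve CSV.
#' @param events_path Path to the JSON/YAML events file (see
#'   [read_events()]).
#' @return A validated [curve_record()].
#' @export
read_curve <- function(path, events_path) {
  rv_assert(file.exists(path), "rv_io_error",
            sprintf("curve file not found: %s", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("time_ms", "strain_pct")) {
    rv_assert(col %in% names(tab), "rv_column_error",
              sprintf("curve file %s is missing column '%s'", path, col))
    rv_assert(is.numeric(tab[[col]]), "rv_numeric_error",
              sprintf("column '%s' in %s contains non-numeric cells", col, path))
  }
  ev <- read_events(events_path)
  curve <- strain_curve(
    subject_id = as.character(ev$subject_id),
    segment = as.character(ev$segment),
    times = tab$time_ms,
    strains = tab$strain_pct,
    framerate_hz = ev$framerate_hz
  )
  events <- cardiac_events(
    qrs_onset_ms = ev$qrs_onset_ms,
    pv_close_ms = ev$pv_close_ms,
    pv_open_ms = ev$pv_open_ms
  )
  curve_record(curve, events, source_path = path)
}

#' Read a cohort manifest
#'
#' A manifest is a JSON array of `{curve, events}` path pairs; relative
#' paths are resolved against the manifest's directory.
#'
#' @param path Path to the manifest JSON.
#' @return A list of [curve_record()] objects, in manifest order.
#' @export
read_manifest <- function(path) {
  rv_assert(file.exists(path), "rv_io_error",
            sprintf("manifest not found: %s", path))
  entries <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rv_assert(length(entries) > 0L, "rv_manifest_error", "manifest is empty")
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  lapply(entries, function(e) {
    rv_assert(!is.null(e$curve) && !is.null(e$events), "rv_manifest_error",
              "each manifest entry needs 'curve' and 'events' paths")
    read_curve(resolve(e$curve), resolve(e$events))
  })
}

#' Write a per-curve metrics and classification table
#'
#' One row per analyzed curve: identity, the four deformation parameters,
#' the per-parameter points, the total, the pattern type, and an `errors`
#' column (empty for successful curves, the failure message for curves that
#' could not be analyzed). Times are printed at 0.1 ms resolution and strain
#' values at 0.01%.
#'
#' @param results A non-empty list whose elements are lists with a `record`
#'   element plus either `metrics` and `classification` (see
#'   [analyze_curve()]) or an `error` message string.
#' @param path Output CSV path.
#' @return The written data frame, invisibly.
#' @export
write_metrics <- function(results, path) {
  rv_assert(is.list(results) && length(results) > 0L, "rv_length_error",
            "results must be a non-empty list")
  rows <- lapply(results, function(res) {
    rv_assert(!is.null(res$record) ||
                (!is.null(res$error) && !is.null(res$subject_id)),
              "rv_field_error",
              "each result needs a 'record' (or 'error' with 'subject_id')")
    rec <- res$record
    if (!is.null(res$error)) {
      data.frame(subject_id = if (is.null(rec)) as.character(res$subject_id)
                              else rec$curve$subject_id,
                 segment = if (is.null(rec)) {
                   if (is.null(res$segment)) NA_character_
                   else as.character(res$segment)
                 } else rec$curve$segment,
                 onset_ms = NA_real_, peak_strain_pct = NA_real_,
                 systolic_peak_strain_pct = NA_real_, psi_pct = NA_real_,
                 points_onset = NA_integer_, points_psi = NA_integer_,
                 points_sps = NA_integer_, points_total = NA_integer_,
                 type = NA_character_, errors = as.character(res$error),
                 stringsAsFactors = FALSE)
    } else {
      m <- res$metrics
      cl <- res$classification
      rv_assert(!is.null(m) && !is.null(cl), "rv_field_error",
                "each result needs 'metrics' and 'classification' (or 'error')")
      data.frame(subject_id = rec$curve$subject_id,
                 segment = rec$curve$segment,
                 onset_ms = round(m$onset_ms, 1),
                 peak_strain_pct = round(m$peak_strain_pct, 2),
                 systolic_peak_strain_pct = round(m$systolic_peak_strain_pct, 2),
                 psi_pct = round(m$psi_pct, 2),
                 points_onset = cl$points_onset,
                 points_psi = cl$points_psi,
                 points_sps = cl$points_sps,
                 points_total = cl$points_total,
                 type = cl$pattern_type, errors = "",
                 stringsAsFactors = FALSE)
    }
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE)
  invisible(tab)
}

#' @export
print.curve_record <- function(x, ...) {
  cat(sprintf("<curve_record> subject %s, %s segment: %d samples over [%.1f, %.1f] ms\n",
              x$curve$subject_id, x$curve$segment, length(x$curve$times),
              min(x$curve$times), max(x$curve$times)))
  cat(sprintf("  QRS onset %.1f ms, PV closure %.1f ms%s\n",
              x$events$qrs_onset_ms, x$events$pv_close_ms,
              if (is.null(x$events$pv_open_ms)) ""
              else sprintf(", PV opening %.1f ms", x$events$pv_open_ms)))
  invisible(x)
}
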