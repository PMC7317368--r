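#' Peak strain
#'
#' The maximal negative strain value, i.e. the minimum of the strain curve
#' over the whole prepared window (contraction and relaxation).
#'
#' @param prepared A [prepare_curve()] result.
#' @return Strain in percent.
#' @export
peak_strain <- function(prepared) {
  rv_assert(inherits(prepared, "prepared_curve"), "rv_field_error",
            "prepared must be a prepared_curve")
  min(prepared$strains)
}

#' Systolic peak strain
#'
#' The minimal strain value before or at pulmonary valve closure (PVC).
#' The boundary is inclusive: when the uniform grid does not land exactly
#' on the PVC time, the strain at PVC is obtained by linear interpolation
#' and included in the minimum.
#'
#' @param prepared A [prepare_curve()] result.
#' @return Strain in percent; always >= [peak_strain()].
#' @export
systolic_peak_strain <- function(prepared) {
  rv_assert(inherits(prepared, "prepared_curve"), "rv_field_error",
            "prepared must be a prepared_curve")
  pvc <- prepared$pv_close_rel_ms
  before <- prepared$strains[prepared$rel_times <= pvc]
  at_pvc <- stats::approx(prepared$rel_times, prepared$strains, xout = pvc)$y
  min(c(before, at_pvc))
}

#' Post-systolic index
#'
#' `PSI = 100 * (PS - SPS) / PS`, the fraction of total shortening that
#' occurs after pulmonary valve closure, with PS the peak strain and SPS
#' the systolic peak strain. When the peak strain equals the systolic peak
#' strain the PSI is defined to be zero. PSI is non-negative whenever
#' PS < 0, stays at or below 100 while SPS <= 0, and can exceed 100 for
#' curves with systolic stretching (SPS > 0).
#'
#' @param ps Peak strain in percent (must be <= `sps`).
#' @param sps Systolic peak strain in percent.
#' @return PSI in percent.
#' @export
postsystolic_index <- function(ps, sps) {
  rv_assert(is_scalar_number(ps) && is_scalar_number(sps),
            "rv_numeric_error", "ps and sps must be finite numbers")
  rv_assert(ps <= sps, "rv_field_error",
            "peak strain must not exceed systolic peak strain")
  if (ps == sps) return(0)
  rv_assert(ps != 0, "rv_psi_error",
            "PSI is undefined for zero peak strain with sps != ps")
  100 * (ps - sps) / ps
}

band_points <- function(bands, value, what) {
  for (b in bands) if (value <= b$upper) return(as.integer(b$points))
  rv_error("rv_rubric_error",
           sprintf("rubric bands for %s do not cover value %g", what, value))
}

band_type <- function(bands, total) {
  for (b in bands) if (total <= b$upper) return(as.character(b$type))
  rv_error("rv_rubric_error",
           sprintf("rubric type bands do not cover total %d", total))
}

validate_bands <- function(bands, what) {
  rv_assert(is.list(bands) && length(bands) > 0L, "rv_rubric_error",
            sprintf("rubric is missing %s", what))
  uppers <- vapply(bands, function(b) as.numeric(b$upper), numeric(1))
  rv_assert(!is.unsorted(uppers, strictly = TRUE), "rv_rubric_error",
            sprintf("%s upper bounds must be strictly increasing", what))
  rv_assert(is.infinite(uppers[length(uppers)]), "rv_rubric_error",
            sprintf("last %s band must have an infinite upper bound", what))
  bands
}

#' Read a deformation-pattern scoring rubric
#'
#' The rubric is a YAML document giving, for each scored parameter, ordered
#' `(upper bound -> points)` bands (`value <= upper` selects the first
#' matching band; the last band is unbounded), plus `sps_shortcut_pct` and
#' the `(total points -> type)` bands. The shortcut rule — a systolic peak
#' strain at or above `sps_shortcut_pct` scores 4 points outright and
#' forces type III, without scoring onset or PSI — is applied before any
#' band lookup.
#'
#' @param path Path to the rubric YAML.
#' @return An object of class `deformation_rubric`.
#' @seealso [default_rubric()]
#' @export
read_rubric <- function(path) {
  rv_assert(file.exists(path), "rv_io_error",
            sprintf("rubric file not found: %s", path))
  raw <- yaml::read_yaml(path)
  rv_assert(is_scalar_number(raw$sps_shortcut_pct), "rv_rubric_error",
            "rubric needs a numeric sps_shortcut_pct")
  rubric <- list(
    sps_shortcut_pct = raw$sps_shortcut_pct,
    shortcut_points = if (is.null(raw$shortcut_points)) 4L
                      else as.integer(raw$shortcut_points),
    onset_bands = validate_bands(raw$onset_bands, "onset_bands"),
    psi_bands = validate_bands(raw$psi_bands, "psi_bands"),
    sps_bands = validate_bands(raw$sps_bands, "sps_bands"),
    type_bands = raw$type_bands
  )
  rv_assert(is.list(rubric$type_bands) && length(rubric$type_bands) > 0L,
            "rv_rubric_error", "rubric needs type_bands")
  structure(rubric, class = "deformation_rubric")
}

#' Default scoring rubric
#'
#' Loads the rubric shipped with the package
#' (`inst/extdata/rubric_default.yaml`). Its text-anchored rules are: a
#' systolic peak strain >= -10% scores 4 points and is type III outright,
#' and totals of 4–6 points map to type III. The remaining band cut-offs
#' are package defaults kept in the reviewable YAML file rather than in
#' code, so a laboratory can substitute its own calibration.
#'
#' @return A `deformation_rubric`.
#' @export
default_rubric <- function() {
  read_rubric(system.file("extdata", "rubric_default.yaml",
                          package = "rvdeform", mustWork = TRUE))
}

#' Score a curve's deformation parameters and classify its pattern
#'
#' Applies the points-based rubric. First the shortcut: a curve whose
#' systolic peak strain never drops below -10% (SPS >= -10, inclusive)
#' receives 4 points and is marked type III directly; its onset and PSI
#' are not scored (their points are reported as 0 and the `sps_shortcut`
#' flag is set). Otherwise each of onset of shortening, PSI, and SPS is
#' scored through its bands, the points are summed, and the total is
#' mapped to pattern type I, II, or III.
#'
#' @param metrics A `deformation_metrics` list with `onset_ms`,
#'   `peak_strain_pct`, `systolic_peak_strain_pct`, `psi_pct` (see
#'   [analyze_curve()]); `onset_ms`/`psi_pct` may be `NA` only when the
#'   shortcut applies.
#' @param rubric A `deformation_rubric` (default: [default_rubric()]).
#' @return An object of class `classification_result` with per-parameter
#'   points, `points_total`, `pattern_type` and the `sps_shortcut` flag.
#' @export
score_deformation <- function(metrics, rubric = default_rubric()) {
  rv_assert(inherits(rubric, "deformation_rubric"), "rv_field_error",
            "rubric must be a deformation_rubric")
  sps <- metrics$systolic_peak_strain_pct
  rv_assert(is_scalar_number(sps), "rv_numeric_error",
            "metrics$systolic_peak_strain_pct must be a finite number")
  if (sps >= rubric$sps_shortcut_pct) {
    pts <- rubric$shortcut_points
    res <- list(points_onset = 0L, points_psi = 0L, points_sps = pts,
                points_total = pts, pattern_type = "III",
                sps_shortcut = TRUE)
  } else {
    p_on <- band_points(rubric$onset_bands, metrics$onset_ms, "onset")
    p_psi <- band_points(rubric$psi_bands, metrics$psi_pct, "PSI")
    p_sps <- band_points(rubric$sps_bands, sps, "SPS")
    total <- p_on + p_psi + p_sps
    res <- list(points_onset = p_on, points_psi = p_psi, points_sps = p_sps,
                points_total = total,
                pattern_type = band_type(rubric$type_bands, total),
                sps_shortcut = FALSE)
  }
  structure(res, class = "classification_result")
}

#' Analyze one strain curve end to end
#'
#' Runs the full pipeline on a validated record: preprocessing
#' (re-referencing to QRS onset and resampling to `n_samples`), onset
#' detection, the PS/SPS/PSI parameters, and the points-based
#' classification. Deterministic; completes without user interaction.
#'
#' @param record A [curve_record()].
#' @param rubric A `deformation_rubric` (default: [default_rubric()]).
#' @param n_samples Resampling grid size (default 1000).
#' @param onset_threshold Peak-offset threshold in percent strain
#'   (default 1.5).
#' @return A list with `metrics` (class `deformation_metrics`),
#'   `classification` (class `classification_result`), `onset` (the full
#'   [onset_of_shortening()] result) and `prepared` (the resampled curve).
#' @export
analyze_curve <- function(record, rubric = default_rubric(),
                          n_samples = 1000L, onset_threshold = 1.5) {
  prepared <- prepare_curve(record, n_samples)
  ons <- onset_of_shortening(prepared, onset_threshold)
  ps <- peak_strain(prepared)
  sps <- systolic_peak_strain(prepared)
  # ps == 0 with sps > ps cannot happen (sps >= ps by construction and a
  # zero PS forces the -10% shortcut), but PSI is left NA defensively.
  psi <- if (ps == sps) 0 else if (ps == 0) NA_real_ else 100 * (ps - sps) / ps
  metrics <- structure(
    list(onset_ms = ons$onset_ms, peak_strain_pct = ps,
         systolic_peak_strain_pct = sps, psi_pct = psi),
    class = "deformation_metrics"
  )
  list(metrics = metrics,
       classification = score_deformation(metrics, rubric),
       onset = ons, prepared = prepared)
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> type %s (%d points: onset %d, PSI %d, SPS %d)%s\n",
              x$pattern_type, x$points_total, x$points_onset, x$points_psi,
              x$points_sps,
              if (x$sps_shortcut) " [SPS >= -10% shortcut]" else ""))
  invisible(x)
}

#' @export
print.deformation_metrics <- function(x, ...) {
  cat(sprintf("<deformation_metrics> onset %.1f ms, PS %.2f%%, SPS %.2f%%, PSI %.1f%%\n",
              x$onset_ms, x$peak_strain_pct, x$systolic_peak_strain_pct,
              x$psi_pct))
  invisible(x)
}
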