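#' Native frame duration from framerate
#'
#' The duration between two imaging frames, `1000 / framerate_hz` ms. This
#' is the temporal resolution floor of any onset timing: at a typical 75 Hz
#' acquisition one frame lasts ~13 ms.
#'
#' @param framerate_hz Acquisition framerate in Hz (> 0).
#' @return Frame duration in ms.
#' @export
frame_duration <- function(framerate_hz) {
  rv_assert(is_scalar_number(framerate_hz) && framerate_hz > 0,
            "rv_field_error", "framerate_hz must be a positive number")
  1000 / framerate_hz
}

#' Re-reference and resample a strain curve
#'
#' Restricts the curve to the window from QRS onset to the last native
#' sample, shifts time so that QRS onset is 0, and linearly interpolates
#' onto a uniform grid of `n_samples` points. Putting every curve on the
#' same fine grid makes onset times comparable across curves regardless of
#' the native framerate. Interpolation is linear on purpose: it introduces
#' no extrema that are not in the data, which matters because the onset
#' detector counts local maxima. Strain values are kept as read (not
#' re-zeroed at QRS onset) because the 1.5% peak-offset rule and the -10%
#' cutoff are absolute comparisons on the curve as drawn.
#'
#' @param record A validated [curve_record()].
#' @param n_samples Number of grid points (default 1000).
#' @return An object of class `prepared_curve` with fields `rel_times`
#'   (ms, 0 at QRS onset, uniform spacing), `strains`, `pv_close_rel_ms`,
#'   `pv_open_rel_ms` (or `NULL`), and `native_frame_ms` (from the recorded
#'   framerate when available, else the median native sample interval).
#' @export
prepare_curve <- function(record, n_samples = 1000L) {
  rv_assert(inherits(record, "curve_record"), "rv_field_error",
            "record must be a curve_record")
  rv_assert(is_scalar_number(n_samples) && n_samples >= 3 &&
              n_samples == round(n_samples),
            "rv_field_error", "n_samples must be an integer >= 3")
  qrs <- record$events$qrs_onset_ms
  pvc <- record$events$pv_close_ms
  rv_assert(pvc > qrs, "rv_event_order_error",
            "pv_close_ms must lie after qrs_onset_ms")
  t_nat <- record$curve$times
  rv_assert(sum(t_nat >= qrs) >= 3L, "rv_window_error",
            "fewer than 3 native samples between QRS onset and curve end")
  t_end <- t_nat[length(t_nat)] - qrs
  grid <- seq(0, t_end, length.out = n_samples)
  y <- stats::approx(t_nat - qrs, record$curve$strains, xout = grid)$y
  native_frame_ms <- if (!is.null(record$curve$framerate_hz)) {
    frame_duration(record$curve$framerate_hz)
  } else {
    stats::median(diff(t_nat))
  }
  structure(
    list(rel_times = grid, strains = y,
         pv_close_rel_ms = pvc - qrs,
         pv_open_rel_ms = if (is.null(record$events$pv_open_ms)) NULL
                          else record$events$pv_open_ms - qrs,
         native_frame_ms = native_frame_ms),
    class = "prepared_curve"
  )
}

#' @export
print.prepared_curve <- function(x, ...) {
  cat(sprintf("<prepared_curve> %d samples over [0, %.1f] ms, PVC at %.1f ms, native frame %.2f ms\n",
              length(x$rel_times), max(x$rel_times), x$pv_close_rel_ms,
              x$native_frame_ms))
  invisible(x)
}
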