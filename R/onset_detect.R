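#' Local strain maxima before pulmonary valve closure
#'
#' A peak is a local maximum: a data point larger than both neighboring
#' data points. Only the curve segment strictly before pulmonary valve
#' closure (PVC) is searched, because mechanical shortening always starts
#' before PVC. A plateau (two or more equal values higher than both flanks,
#' which uniform-grid interpolation of flat segments readily creates) is
#' reported once, at its first sample. No prominence filtering is applied:
#' every strict local maximum counts.
#'
#' @param prepared A [prepare_curve()] result.
#' @return A data frame with columns `index` (sample index into the
#'   prepared grid), `time_ms`, `strain_pct`, in time order. Zero rows when
#'   no peak exists.
#' @export
find_strain_peaks <- function(prepared) {
  rv_assert(inherits(prepared, "prepared_curve"), "rv_field_error",
            "prepared must be a prepared_curve")
  y <- prepared$strains
  t <- prepared$rel_times
  runs <- rle(y)
  nr <- length(runs$values)
  idx <- integer(0)
  if (nr >= 3L) {
    starts <- cumsum(c(1L, runs$lengths[-nr]))
    for (j in 2:(nr - 1L)) {
      if (runs$values[j] > runs$values[j - 1L] &&
          runs$values[j] > runs$values[j + 1L]) {
        idx <- c(idx, starts[j])
      }
    }
  }
  keep <- t[idx] > 0 & t[idx] < prepared$pv_close_rel_ms
  idx <- idx[keep]
  data.frame(index = as.integer(idx), time_ms = t[idx], strain_pct = y[idx])
}

#' Select the onset-of-shortening peak from a peak list
#'
#' Implements the iterative peak-selection rule. With zero peaks nothing is
#' selected; with one peak it is taken. With several, the first peak is the
#' running candidate and each subsequent peak is compared against it in
#' time order: when the next peak lies more than `threshold` percent
#' absolute strain below the candidate (strict inequality), the candidate
#' wins and iteration stops; otherwise the next peak becomes the candidate.
#' If the list is exhausted, the surviving candidate is returned. Only
#' strain *offsets* between peaks matter, so the rule is invariant to
#' adding a constant to the whole curve — but not to rescaling amplitude,
#' since the threshold is absolute strain.
#'
#' @param peaks A peak table from [find_strain_peaks()].
#' @param threshold Strain offset in percent (default 1.5).
#' @return A one-row data frame (the selected peak) or `NULL` when `peaks`
#'   is empty.
#' @export
select_onset_peak <- function(peaks, threshold = 1.5) {
  rv_assert(is.data.frame(peaks) &&
              all(c("index", "time_ms", "strain_pct") %in% names(peaks)),
            "rv_field_error", "peaks must come from find_strain_peaks()")
  rv_assert(is_scalar_number(threshold) && threshold >= 0,
            "rv_field_error", "threshold must be a non-negative number")
  n <- nrow(peaks)
  if (n == 0L) return(NULL)
  cand <- 1L
  if (n > 1L) {
    for (p in 2:n) {
      if (peaks$strain_pct[cand] - peaks$strain_pct[p] > threshold) break
      cand <- p
    }
  }
  peaks[cand, , drop = FALSE]
}

#' Onset of mechanical shortening
#'
#' The onset of shortening is the time from QRS onset to the start of
#' mechanical shortening, located at the selected pre-PVC strain peak (see
#' [find_strain_peaks()] and [select_onset_peak()]). When no peak exists
#' before PVC the onset is assumed to be at the QRS onset itself
#' (`onset_ms = 0`).
#'
#' @param prepared A [prepare_curve()] result.
#' @param threshold Peak-offset threshold in percent strain (default 1.5).
#' @return An object of class `onset_result`: `onset_ms` (>= 0, always
#'   before PVC), `selected_peak_index` (grid index, `NA` under the no-peak
#'   fallback), `n_peaks_considered`.
#' @export
onset_of_shortening <- function(prepared, threshold = 1.5) {
  peaks <- find_strain_peaks(prepared)
  sel <- select_onset_peak(peaks, threshold)
  res <- if (is.null(sel)) {
    list(onset_ms = 0, selected_peak_index = NA_integer_,
         n_peaks_considered = 0L)
  } else {
    list(onset_ms = sel$time_ms, selected_peak_index = sel$index,
         n_peaks_considered = nrow(peaks))
  }
  structure(res, class = "onset_result")
}

#' @export
print.onset_result <- function(x, ...) {
  if (is.na(x$selected_peak_index)) {
    cat("<onset_result> no pre-PVC peak; onset at QRS onset (0 ms)\n")
  } else {
    cat(sprintf("<onset_result> onset %.1f ms (grid index %d; %d peak(s) considered)\n",
                x$onset_ms, x$selected_peak_index, x$n_peaks_considered))
  }
  invisible(x)
}
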