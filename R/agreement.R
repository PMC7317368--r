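# Agreement statistics between two sets of onset annotations (algorithm vs
# operator, or operator vs operator): Bland-Altman, median/IQR of absolute
# differences, rank correlation, ICC(2,1), and time-frame differences.

#' Construct a paired-onset table
#'
#' @param curve_ids Curve identifiers.
#' @param onsets_a,onsets_b Onset-of-shortening times in ms (>= 0), equal
#'   length >= 2.
#' @param frame_ms Per-curve native frame duration in ms (> 0); recycled if
#'   scalar.
#' @return A data frame of class `paired_onsets`.
#' @export
paired_onsets <- function(curve_ids, onsets_a, onsets_b, frame_ms) {
  n <- length(onsets_a)
  rv_assert(length(onsets_b) == n && length(curve_ids) == n,
            "rv_length_error", "curve_ids, onsets_a, onsets_b must have equal length")
  rv_assert(n >= 2L, "rv_length_error", "need at least 2 paired onsets")
  if (length(frame_ms) == 1L) frame_ms <- rep(frame_ms, n)
  rv_assert(length(frame_ms) == n, "rv_length_error",
            "frame_ms must be scalar or match the number of curves")
  rv_assert(all(is.finite(onsets_a)) && all(is.finite(onsets_b)) &&
              all(onsets_a >= 0) && all(onsets_b >= 0),
            "rv_numeric_error", "onsets must be finite and >= 0")
  rv_assert(all(is.finite(frame_ms)) && all(frame_ms > 0),
            "rv_numeric_error", "frame durations must be positive")
  structure(
    data.frame(curve_id = as.character(curve_ids),
               onset_a_ms = as.numeric(onsets_a),
               onset_b_ms = as.numeric(onsets_b),
               frame_ms = as.numeric(frame_ms),
               stringsAsFactors = FALSE),
    class = c("paired_onsets", "data.frame")
  )
}

#' Read paired onsets from CSV
#'
#' Expects columns `curve_id`, `onset_a_ms`, `onset_b_ms`, `frame_ms`.
#'
#' @param path CSV path.
#' @return A [paired_onsets()] table.
#' @export
read_pairs <- function(path) {
  rv_assert(file.exists(path), "rv_io_error",
            sprintf("pairs file not found: %s", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("curve_id", "onset_a_ms", "onset_b_ms", "frame_ms")) {
    rv_assert(col %in% names(tab), "rv_column_error",
              sprintf("pairs file %s is missing column '%s'", path, col))
  }
  paired_onsets(tab$curve_id, tab$onset_a_ms, tab$onset_b_ms, tab$frame_ms)
}

# ICC(2,1): two-way random effects, absolute agreement, single measurement,
# computed from the two-way ANOVA mean squares, with the F-based confidence
# interval of McGraw & Wong. `mat` is subjects x raters.
icc_a1 <- function(mat, conf_level = 0.95) {
  n <- nrow(mat)
  k <- ncol(mat)
  grand <- mean(mat)
  row_m <- rowMeans(mat)
  col_m <- colMeans(mat)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  resid <- mat - matrix(row_m, n, k) - matrix(col_m, n, k, byrow = TRUE) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  eps <- 1e-12
  if (mse < eps && msc < eps) {
    # Perfect agreement: no rater effect and no residual disagreement.
    return(list(icc = 1, lower = 1, upper = 1))
  }
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf_level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(icc = icc, lower = lower, upper = upper)
}

#' Compare two sets of onset annotations
#'
#' Computes the full agreement report between annotation sets `a` and `b`:
#' Bland-Altman statistics on the signed differences `a - b` (mean, SD,
#' limits of agreement at +/- 1.96 SD), median and IQR of the absolute
#' differences, Spearman's rho (with Pearson's r alongside), ICC(2,1)
#' (two-way random effects, absolute agreement, single measurement) with
#' its 95% F-based confidence interval, and the fraction of curves whose
#' absolute difference is within one native time frame.
#'
#' @param pairs A [paired_onsets()] table.
#' @param use_global_frame When `TRUE`, the time-frame statistic divides
#'   every difference by the cohort mean frame duration instead of the
#'   per-curve one.
#' @param conf_level Confidence level for the ICC interval (default 0.95).
#' @return An object of class `agreement_report`.
#' @export
compare_onsets <- function(pairs, use_global_frame = FALSE,
                           conf_level = 0.95) {
  rv_assert(inherits(pairs, "paired_onsets"), "rv_field_error",
            "pairs must be a paired_onsets table")
  a <- pairs$onset_a_ms
  b <- pairs$onset_b_ms
  d <- a - b
  ad <- abs(d)
  mean_diff <- mean(d)
  sd_diff <- stats::sd(d)
  q <- stats::quantile(ad, c(0.25, 0.75), names = FALSE)
  rho_test <- tryCatch(
    suppressWarnings(stats::cor.test(a, b, method = "spearman",
                                     exact = FALSE)),
    error = function(e) NULL
  )
  pearson <- suppressWarnings(stats::cor(a, b))
  icc <- icc_a1(cbind(a, b), conf_level)
  frames <- if (use_global_frame) rep(mean(pairs$frame_ms), length(ad))
            else pairs$frame_ms
  structure(
    list(n = length(d),
         mean_diff_ms = mean_diff, sd_diff_ms = sd_diff,
         loa_low_ms = mean_diff - 1.96 * sd_diff,
         loa_high_ms = mean_diff + 1.96 * sd_diff,
         median_abs_diff_ms = stats::median(ad),
         iqr_abs_diff_ms = q,
         rho = if (is.null(rho_test)) NA_real_
               else unname(rho_test$estimate),
         rho_p = if (is.null(rho_test)) NA_real_ else rho_test$p.value,
         pearson_r = unname(pearson),
         icc = icc$icc, icc_ci = c(icc$lower, icc$upper),
         frac_within_1_frame = mean(ad / frames <= 1)),
    class = "agreement_report"
  )
}

#' Compare two classification label sets
#'
#' @param types_a,types_b Equal-length vectors of pattern types
#'   (`"I"`/`"II"`/`"III"`), length >= 1.
#' @return A list with `agreement` (fraction of exact matches) and
#'   `confusion` (3x3 table, `a` in rows, `b` in columns).
#' @export
compare_classifications <- function(types_a, types_b) {
  rv_assert(length(types_a) == length(types_b), "rv_length_error",
            "types_a and types_b must have equal length")
  rv_assert(length(types_a) >= 1L, "rv_length_error",
            "need at least one classification pair")
  lv <- c("I", "II", "III")
  rv_assert(all(types_a %in% lv) && all(types_b %in% lv),
            "rv_field_error", "types must be 'I', 'II' or 'III'")
  fa <- factor(types_a, levels = lv)
  fb <- factor(types_b, levels = lv)
  list(agreement = mean(fa == fb),
       confusion = table(a = fa, b = fb))
}

#' Bland-Altman plot of paired onsets
#'
#' Scatter of per-curve means against signed differences `a - b`, with the
#' mean difference and the +/- 1.96 SD limits of agreement as horizontal
#' lines.
#'
#' @param pairs A [paired_onsets()] table.
#' @param file Optional PNG path; when given the plot is written there
#'   instead of the active device.
#' @return The [compare_onsets()] report, invisibly.
#' @export
plot_bland_altman <- function(pairs, file = NULL) {
  rep <- compare_onsets(pairs)
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 600)
    on.exit(grDevices::dev.off())
  }
  m <- (pairs$onset_a_ms + pairs$onset_b_ms) / 2
  d <- pairs$onset_a_ms - pairs$onset_b_ms
  graphics::plot(m, d, pch = 19, col = "grey30",
                 xlab = "Mean onset of shortening (ms)",
                 ylab = "Difference a - b (ms)",
                 main = "Bland-Altman: onset of shortening")
  graphics::abline(h = rep$mean_diff_ms, col = "red", lwd = 2)
  graphics::abline(h = c(rep$loa_low_ms, rep$loa_high_ms),
                   col = "red", lty = 2)
  invisible(rep)
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n = %d curves\n", x$n))
  cat(sprintf("  mean diff %.2f ms (SD %.2f), LoA [%.2f, %.2f] ms\n",
              x$mean_diff_ms, x$sd_diff_ms, x$loa_low_ms, x$loa_high_ms))
  cat(sprintf("  median |diff| %.2f ms (IQR %.2f-%.2f)\n",
              x$median_abs_diff_ms, x$iqr_abs_diff_ms[1],
              x$iqr_abs_diff_ms[2]))
  cat(sprintf("  Spearman rho %.3f (P = %.2g), Pearson r %.3f\n",
              x$rho, x$rho_p, x$pearson_r))
  cat(sprintf("  ICC(2,1) %.3f (95%% CI %.3f-%.3f)\n",
              x$icc, x$icc_ci[1], x$icc_ci[2]))
  cat(sprintf("  within 1 time frame: %.1f%%\n",
              100 * x$frac_within_1_frame))
  invisible(x)
}
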