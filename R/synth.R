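# Synthetic strain-curve generator: piecewise cosine-ramp curves with known
# ground truth, standing in for clinical speckle-tracking data in all tests.

#' Specify a synthetic strain curve
#'
#' Ground-truth parameters from which [generate_curve()] builds a curve.
#' The morphology follows the three deformation-pattern types: type I is a
#' near-normal curve (early onset, deep systolic peak, little post-systolic
#' shortening); type II has a delayed onset with a visible pre-stretch
#' bump, reduced systolic peak strain and post-systolic shortening; type
#' III has a systolic peak strain of -10% or better (systolic stretching
#' with most shortening after valve closure).
#'
#' PS, SPS and PSI are linked by `PSI = 100 * (PS - SPS) / PS`; supply any
#' two of `ps_true_pct`/`psi_true_pct` (the third is derived), or all three
#' consistently (tolerance 0.1 PSI points).
#'
#' @param pattern_type `"I"`, `"II"` or `"III"`.
#' @param onset_true_ms True onset of shortening, ms from QRS onset; must
#'   be positive only when `prestretch_amp_pct > 0` (the pre-stretch bump
#'   is what marks the onset on the curve).
#' @param sps_true_pct True systolic peak strain, %.
#' @param ps_true_pct True peak strain, % (<= `sps_true_pct`).
#' @param psi_true_pct True post-systolic index, %.
#' @param prestretch_amp_pct Pre-stretch bump amplitude, % (>= 0).
#' @param pvc_ms Pulmonary valve closure, ms from QRS onset (default 350).
#' @param cycle_ms Cycle length, ms (default 800).
#' @param framerate_hz Sampling framerate, Hz (default 75, a typical RV
#'   focused acquisition).
#' @param noise_sd_pct Standard deviation of smooth additive noise, %
#'   strain (default 0).
#' @param seed RNG seed for the noise (default 1).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(pattern_type, onset_true_ms, sps_true_pct,
                           ps_true_pct = NULL, psi_true_pct = NULL,
                           prestretch_amp_pct = 0, pvc_ms = 350,
                           cycle_ms = 800, framerate_hz = 75,
                           noise_sd_pct = 0, seed = 1L) {
  rv_assert(pattern_type %in% c("I", "II", "III"), "rv_spec_error",
            "pattern_type must be 'I', 'II' or 'III'")
  rv_assert(is_scalar_number(sps_true_pct), "rv_spec_error",
            "sps_true_pct must be a finite number")
  if (is.null(ps_true_pct) && is.null(psi_true_pct)) {
    rv_error("rv_spec_error",
             "supply ps_true_pct or psi_true_pct (or both, consistently)")
  }
  if (is.null(ps_true_pct)) {
    rv_assert(is_scalar_number(psi_true_pct) && psi_true_pct >= 0,
              "rv_spec_error", "psi_true_pct must be a non-negative number")
    ps_true_pct <- if (psi_true_pct == 0) sps_true_pct
                   else sps_true_pct / (1 - psi_true_pct / 100)
  }
  rv_assert(is_scalar_number(ps_true_pct) && ps_true_pct <= sps_true_pct,
            "rv_spec_error", "ps_true_pct must be <= sps_true_pct")
  psi_model <- if (ps_true_pct == sps_true_pct) 0
               else 100 * (ps_true_pct - sps_true_pct) / ps_true_pct
  if (is.null(psi_true_pct)) {
    psi_true_pct <- psi_model
  } else {
    rv_assert(abs(psi_true_pct - psi_model) <= 0.1, "rv_spec_error",
              sprintf("psi_true_pct (%.2f) inconsistent with ps/sps pair (implies %.2f)",
                      psi_true_pct, psi_model))
  }
  rv_assert(is_scalar_number(onset_true_ms) && onset_true_ms >= 0,
            "rv_spec_error", "onset_true_ms must be >= 0")
  rv_assert(is_scalar_number(prestretch_amp_pct) && prestretch_amp_pct >= 0,
            "rv_spec_error", "prestretch_amp_pct must be >= 0")
  rv_assert(onset_true_ms == 0 || prestretch_amp_pct > 0, "rv_spec_error",
            "a positive onset_true_ms requires a positive pre-stretch bump")
  rv_assert(onset_true_ms < pvc_ms && pvc_ms < cycle_ms, "rv_spec_error",
            "need onset_true_ms < pvc_ms < cycle_ms")
  if (pattern_type == "III") {
    rv_assert(sps_true_pct >= -10, "rv_spec_error",
              "type III requires sps_true_pct >= -10")
  }
  rv_assert(is_scalar_number(framerate_hz) && framerate_hz > 0,
            "rv_spec_error", "framerate_hz must be positive")
  rv_assert(is_scalar_number(noise_sd_pct) && noise_sd_pct >= 0,
            "rv_spec_error", "noise_sd_pct must be >= 0")
  structure(
    list(pattern_type = pattern_type, onset_true_ms = onset_true_ms,
         sps_true_pct = sps_true_pct, ps_true_pct = ps_true_pct,
         psi_true_pct = psi_true_pct,
         prestretch_amp_pct = prestretch_amp_pct, pvc_ms = pvc_ms,
         cycle_ms = cycle_ms, framerate_hz = framerate_hz,
         noise_sd_pct = noise_sd_pct, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# Half-cosine ramp from y0 at t0 to y1 at t1; flat slope at both ends, so
# joining ramps never creates extrema beyond the knots themselves.
cos_ramp <- function(t, t0, t1, y0, y1) {
  y0 + (y1 - y0) * (1 - cos(pi * (t - t0) / (t1 - t0))) / 2
}

# Continuous ground-truth model: baseline 0 before QRS onset (t < 0);
# optional pre-stretch rise to the bump peak at the true onset; monotone
# descent to SPS exactly at PVC; post-systolic descent to PS (when
# PSI > 0); recovery to baseline by end of cycle. The single pre-PVC local
# maximum sits at onset_true_ms, so the ground-truth peak structure is
# known exactly.
strain_model <- function(t, spec) {
  on <- spec$onset_true_ms
  pvc <- spec$pvc_ms
  cyc <- spec$cycle_ms
  P <- spec$prestretch_amp_pct
  sps <- spec$sps_true_pct
  ps <- spec$ps_true_pct
  t_ps <- pvc + 0.3 * (cyc - pvc)
  y <- numeric(length(t))
  seg <- function(lo, hi) t >= lo & t < hi
  if (on > 0) y[seg(0, on)] <- cos_ramp(t[seg(0, on)], 0, on, 0, P)
  top <- if (on > 0) P else 0
  y[seg(on, pvc)] <- cos_ramp(t[seg(on, pvc)], on, pvc, top, sps)
  if (ps < sps) {
    y[seg(pvc, t_ps)] <- cos_ramp(t[seg(pvc, t_ps)], pvc, t_ps, sps, ps)
    y[seg(t_ps, cyc)] <- cos_ramp(t[seg(t_ps, cyc)], t_ps, cyc, ps, 0)
  } else {
    y[seg(pvc, cyc)] <- cos_ramp(t[seg(pvc, cyc)], pvc, cyc, ps, 0)
  }
  y[t < 0 | t >= cyc] <- 0
  y
}

# Low-pass Gaussian noise: white noise smoothed with a Hann window (>= 3
# samples) then rescaled to the target sd. Raw white noise would litter the
# interpolated grid with spurious local maxima that framerate-limited,
# tracker-smoothed clinical curves do not show.
smooth_noise <- function(n, sd, window = 5L) {
  e <- stats::rnorm(n)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, window - 1) / (window - 1))
  w <- w / sum(w)
  pad <- (window - 1L) %/% 2L
  padded <- c(rep(e[1], pad), e, rep(e[n], pad))
  sm <- as.numeric(stats::filter(padded, w, sides = 2))
  sm <- sm[(pad + 1L):(pad + n)]
  sm * sd / stats::sd(sm)
}

#' Generate a synthetic strain curve record
#'
#' Samples the continuous ground-truth model of a [synthetic_spec()] at the
#' spec's framerate, adds smooth seeded noise, and packages the result as a
#' [curve_record()] with a three-frame lead-in before the QRS onset (so the
#' re-referencing step is exercised). Deterministic given the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @param subject_id,segment Identity metadata for the generated record.
#' @return A [curve_record()].
#' @export
generate_curve <- function(spec, subject_id = "synthetic",
                           segment = "basal") {
  rv_assert(inherits(spec, "synthetic_spec"), "rv_spec_error",
            "spec must be a synthetic_spec")
  frame <- 1000 / spec$framerate_hz
  q0 <- 3 * frame
  t_abs <- seq(0, q0 + spec$cycle_ms, by = frame)
  rv_assert(t_abs[length(t_abs)] >= q0 + spec$pvc_ms, "rv_spec_error",
            "cycle too short to cover pulmonary valve closure at this framerate")
  y <- strain_model(t_abs - q0, spec)
  if (spec$noise_sd_pct > 0) {
    y <- y + with_rng_seed(spec$seed,
                           smooth_noise(length(y), spec$noise_sd_pct))
  }
  curve <- strain_curve(subject_id, segment, t_abs, y,
                        framerate_hz = spec$framerate_hz)
  events <- cardiac_events(
    qrs_onset_ms = q0,
    pv_close_ms = q0 + spec$pvc_ms,
    pv_open_ms = q0 + 0.2 * spec$pvc_ms
  )
  curve_record(curve, events, source_path = "<synthetic>")
}

#' Default per-type parameter ranges for synthetic cohorts
#'
#' Uniform sampling ranges for onset of shortening, systolic peak strain,
#' PSI and pre-stretch amplitude, per pattern type. The ranges sit well
#' inside the default rubric's bands (so a noise-free cohort classifies
#' unambiguously) and are physiologically plausible: normal RV free-wall
#' curves reach -25 to -30% systolic strain with onset shortly after QRS;
#' type II curves show delayed onset, moderate SPS reduction and
#' post-systolic shortening; type III curves stay at or above -10% SPS.
#'
#' @return A named list (`I`, `II`, `III`) of range lists, each with
#'   two-element vectors `onset`, `sps`, `psi`, `prestretch`.
#' @export
default_param_ranges <- function() {
  list(
    I = list(onset = c(20, 80), sps = c(-32, -24), psi = c(0.5, 5),
             prestretch = c(0.5, 1.5)),
    II = list(onset = c(115, 140), sps = c(-19, -16), psi = c(13, 22),
              prestretch = c(2, 4)),
    III = list(onset = c(150, 250), sps = c(-9, -4), psi = c(30, 60),
               prestretch = c(3, 6))
  )
}

#' Generate a synthetic cohort with ground truth
#'
#' Builds `n_subjects * segments` curve records. Each subject is assigned a
#' pattern type by the mix proportions (deterministic largest-remainder
#' apportionment, so `type_mix = c(1, 0, 0)` yields exclusively type I);
#' parameters are drawn uniformly from the per-type ranges, independently
#' per curve. Fully reproducible: two calls with the same seed produce
#' identical cohorts, and each record additionally carries its own noise
#' seed in the ground-truth table.
#'
#' @param n_subjects Number of subjects (default 62, three segments each
#'   giving a 186-curve cohort).
#' @param type_mix Proportions of types I/II/III; must sum to 1.
#' @param segments Segments per subject, 1–3 (basal, mid, apical).
#' @param param_ranges Per-type ranges, see [default_param_ranges()].
#' @param framerate_hz Sampling framerate, Hz.
#' @param noise_sd_pct Noise level, % strain.
#' @param seed Cohort RNG seed.
#' @return A list with `records` (list of [curve_record()]s) and `truth`
#'   (data frame of per-curve ground-truth parameters, one row per record,
#'   same order).
#' @export
generate_cohort <- function(n_subjects = 62L,
                            type_mix = c(I = 0.5, II = 0.3, III = 0.2),
                            segments = 3L,
                            param_ranges = default_param_ranges(),
                            framerate_hz = 75, noise_sd_pct = 0,
                            seed = 1L) {
  rv_assert(is_scalar_number(n_subjects) && n_subjects >= 1,
            "rv_spec_error", "n_subjects must be >= 1")
  rv_assert(length(type_mix) == 3L && all(type_mix >= 0) &&
              abs(sum(type_mix) - 1) < 1e-8,
            "rv_spec_error", "type_mix must be 3 proportions summing to 1")
  rv_assert(segments %in% 1:3, "rv_spec_error", "segments must be 1, 2 or 3")
  seg_names <- c("basal", "mid", "apical")[seq_len(segments)]
  # Largest-remainder apportionment of subjects to types.
  quota <- n_subjects * as.numeric(type_mix)
  counts <- floor(quota)
  rem <- n_subjects - sum(counts)
  if (rem > 0) {
    order_rem <- order(quota - counts, decreasing = TRUE)
    counts[order_rem[seq_len(rem)]] <- counts[order_rem[seq_len(rem)]] + 1
  }
  types <- rep(c("I", "II", "III"), times = counts)
  runif_in <- function(rg) stats::runif(1, rg[1], rg[2])
  out <- with_rng_seed(seed, {
    records <- vector("list", n_subjects * segments)
    truth <- vector("list", n_subjects * segments)
    k <- 0L
    for (i in seq_len(n_subjects)) {
      ty <- types[i]
      rg <- param_ranges[[ty]]
      sid <- sprintf("S%03d", i)
      for (sg in seg_names) {
        k <- k + 1L
        spec <- synthetic_spec(
          pattern_type = ty,
          onset_true_ms = runif_in(rg$onset),
          sps_true_pct = runif_in(rg$sps),
          psi_true_pct = runif_in(rg$psi),
          prestretch_amp_pct = runif_in(rg$prestretch),
          framerate_hz = framerate_hz,
          noise_sd_pct = noise_sd_pct,
          seed = sample.int(.Machine$integer.max, 1)
        )
        records[[k]] <- generate_curve(spec, subject_id = sid, segment = sg)
        truth[[k]] <- data.frame(
          subject_id = sid, segment = sg, pattern_type = ty,
          onset_true_ms = spec$onset_true_ms,
          ps_true_pct = spec$ps_true_pct,
          sps_true_pct = spec$sps_true_pct,
          psi_true_pct = spec$psi_true_pct,
          prestretch_amp_pct = spec$prestretch_amp_pct,
          pvc_ms = spec$pvc_ms, cycle_ms = spec$cycle_ms,
          framerate_hz = spec$framerate_hz,
          noise_sd_pct = spec$noise_sd_pct, seed = spec$seed,
          stringsAsFactors = FALSE
        )
      }
    }
    list(records = records, truth = do.call(rbind, truth))
  })
  out
}

#' Write a synthetic cohort to disk
#'
#' Writes one curve CSV and one events JSON per record, a `manifest.json`
#' of `{curve, events}` path pairs (readable by [read_manifest()]), and a
#' `ground_truth.csv` with the per-curve generating parameters.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  rv_assert(is.list(cohort) && !is.null(cohort$records) &&
              length(cohort$records) > 0L,
            "rv_spec_error", "cohort must come from generate_cohort()")
  dir.create(file.path(dir, "curves"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "events"), recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(cohort$records, function(rec) {
    stem <- sprintf("%s_%s", rec$curve$subject_id, rec$curve$segment)
    curve_rel <- file.path("curves", paste0(stem, ".csv"))
    events_rel <- file.path("events", paste0(stem, ".json"))
    utils::write.csv(
      data.frame(time_ms = round(rec$curve$times, 4),
                 strain_pct = round(rec$curve$strains, 6)),
      file.path(dir, curve_rel), row.names = FALSE, quote = FALSE
    )
    ev <- list(subject_id = rec$curve$subject_id,
               segment = rec$curve$segment,
               qrs_onset_ms = rec$events$qrs_onset_ms,
               pv_open_ms = rec$events$pv_open_ms,
               pv_close_ms = rec$events$pv_close_ms,
               framerate_hz = rec$curve$framerate_hz)
    jsonlite::write_json(ev[!vapply(ev, is.null, logical(1))],
                         file.path(dir, events_rel), auto_unbox = TRUE,
                         digits = NA)
    list(curve = curve_rel, events = events_rel)
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(entries, manifest, auto_unbox = TRUE)
  utils::write.csv(cohort$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
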