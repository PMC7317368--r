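# Independent oracles and fixture builders, deliberately written as literal
# restatements of the rules so they share no code with the implementation.

# Build a prepared_curve directly from a strain vector (uniform grid).
make_prepared <- function(strains, total_ms = 1000, pvc_ms = total_ms / 2,
                          native_frame_ms = 1000 / 75) {
  n <- length(strains)
  structure(
    list(rel_times = seq(0, total_ms, length.out = n),
         strains = as.numeric(strains),
         pv_close_rel_ms = pvc_ms,
         pv_open_rel_ms = NULL,
         native_frame_ms = native_frame_ms),
    class = "prepared_curve"
  )
}

# Exhaustive triplet scan: an interior point strictly above both neighbours,
# strictly before PVC. (Valid for tie-free curves.)
bf_find_peaks <- function(prepared) {
  y <- prepared$strains
  t <- prepared$rel_times
  idx <- integer(0)
  for (i in 2:(length(y) - 1L)) {
    if (y[i] > y[i - 1L] && y[i] > y[i + 1L] &&
        t[i] < prepared$pv_close_rel_ms && t[i] > 0) {
      idx <- c(idx, i)
    }
  }
  idx
}

# Literal simulation of the iterative selection rule: keep the first peak;
# whenever the next peak is more than `thr` percent strain below the current
# one, stop; otherwise move on to it.
bf_select_onset <- function(values, thr = 1.5) {
  if (length(values) == 0L) return(NA_integer_)
  cand <- 1L
  i <- 2L
  while (i <= length(values)) {
    if (values[cand] - values[i] > thr) return(cand)
    cand <- i
    i <- i + 1L
  }
  cand
}

# A two-peak test curve: first peak at `p1` percent, second `offset` below
# it, then a systolic descent. Peaks sit at 100 ms and 200 ms.
two_peak_prepared <- function(offset, p1 = 2, dip = p1 - 3) {
  p2 <- p1 - offset
  t <- seq(0, 600, by = 5)
  y <- numeric(length(t))
  knots_t <- c(0, 100, 150, 200, 450, 600)
  knots_y <- c(0, p1, dip, p2, -20, -5)
  y <- approx(knots_t, knots_y, xout = t)$y
  make_prepared(y, total_ms = 600, pvc_ms = 450)
}

# Random specs drawn uniformly from the package's per-type ranges.
random_specs <- function(n, noise_sd_pct = 0, framerate_hz = 75, seed = 1) {
  ranges <- default_param_ranges()
  withr_seed <- function(expr) rvdeform:::with_rng_seed(seed, expr)
  withr_seed({
    lapply(seq_len(n), function(i) {
      ty <- sample(c("I", "II", "III"), 1)
      rg <- ranges[[ty]]
      synthetic_spec(
        pattern_type = ty,
        onset_true_ms = runif(1, rg$onset[1], rg$onset[2]),
        sps_true_pct = runif(1, rg$sps[1], rg$sps[2]),
        psi_true_pct = runif(1, rg$psi[1], rg$psi[2]),
        prestretch_amp_pct = runif(1, rg$prestretch[1], rg$prestretch[2]),
        framerate_hz = framerate_hz,
        noise_sd_pct = noise_sd_pct,
        seed = sample.int(1e6, 1)
      )
    })
  })
}
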