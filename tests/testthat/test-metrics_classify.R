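test_that("peak strain is the curve minimum; SPS is pre-PVC inclusive", {
  y <- c(0, -3, -12, -8, -22.4, -6)
  prep <- make_prepared(y, total_ms = 500, pvc_ms = 260)
  expect_equal(peak_strain(prep), -22.4)
  # grid: 0,100,...,500; pre-PVC samples reach -12 at 200 ms, and the
  # interpolated value at PVC (260 ms) is -12 + 0.6 * 4 = -9.6
  expect_equal(systolic_peak_strain(prep), -12)

  expect_equal(peak_strain(make_prepared(rep(-5, 10))), -5)

  # monotone decrease through PVC: SPS is the interpolated strain at PVC
  y <- seq(0, -20, length.out = 11)
  prep <- make_prepared(y, total_ms = 1000, pvc_ms = 350)
  expect_equal(systolic_peak_strain(prep), -7)
})

test_that("SPS >= PS on random curves and both match brute-force scans", {
  specs <- random_specs(150, noise_sd_pct = 0.2, seed = 4)
  for (spec in specs) {
    prep <- prepare_curve(generate_curve(spec))
    ps <- peak_strain(prep)
    sps <- systolic_peak_strain(prep)
    expect_identical(ps, min(prep$strains))
    expect_gte(sps, ps)
    oracle <- min(c(prep$strains[prep$rel_times <= prep$pv_close_rel_ms],
                    approx(prep$rel_times, prep$strains,
                           xout = prep$pv_close_rel_ms)$y))
    expect_equal(sps, oracle)
  }
})

test_that("the post-systolic index follows its defining formula", {
  expect_equal(postsystolic_index(-18, -18), 0)
  expect_equal(postsystolic_index(-20, -15), 25)
  expect_equal(postsystolic_index(-10, 0), 100)
  expect_error(postsystolic_index(-10, -12), class = "rv_field_error")
  expect_error(postsystolic_index(0, 3), class = "rv_psi_error")
})

test_that("PSI exceeds 100 exactly for systolic stretching", {
  # SPS > 0 (stretching): PSI > 100
  expect_gt(postsystolic_index(-8, 2), 100)
  # SPS <= 0: PSI <= 100
  expect_lte(postsystolic_index(-8, 0), 100)
  expect_lte(postsystolic_index(-25, -11), 100)
})

metrics_of <- function(onset, ps, sps, psi) {
  structure(list(onset_ms = onset, peak_strain_pct = ps,
                 systolic_peak_strain_pct = sps, psi_pct = psi),
            class = "deformation_metrics")
}

test_that("the -10% shortcut scores 4 points and forces type III", {
  rub <- default_rubric()
  res <- score_deformation(metrics_of(250, -15, -8, 46.7), rub)
  expect_true(res$sps_shortcut)
  expect_equal(res$points_total, 4L)
  expect_equal(res$points_sps, 4L)
  expect_equal(res$points_onset, 0L)
  expect_equal(res$points_psi, 0L)
  expect_equal(res$pattern_type, "III")

  # the boundary is inclusive: SPS of exactly -10.0 triggers the shortcut
  res <- score_deformation(metrics_of(250, -15, -10, 33.3), rub)
  expect_true(res$sps_shortcut)
  expect_equal(res$pattern_type, "III")

  # just below the boundary the full rubric is applied
  res <- score_deformation(metrics_of(40, -22, -10.5, 52.3), rub)
  expect_false(res$sps_shortcut)
})

test_that("every total of 4-6 points maps to type III", {
  rub <- default_rubric()
  # 2 + 2 + 2 = 6, 2 + 2 + 1 = 5, 2 + 2 + 0 = 4 (without the shortcut)
  cases <- list(
    list(m = metrics_of(200, -25, -12, 52), total = 6L),
    list(m = metrics_of(200, -30, -16, 46.7), total = 5L),
    list(m = metrics_of(200, -40, -22, 45), total = 4L)
  )
  for (cs in cases) {
    res <- score_deformation(cs$m, rub)
    expect_equal(res$points_total, cs$total)
    expect_equal(res$pattern_type, "III")
  }
  # and low / mid totals map to types I and II
  expect_equal(score_deformation(metrics_of(40, -28, -26, 7), rub)$pattern_type,
               "I")
  expect_equal(score_deformation(metrics_of(120, -20, -17, 15), rub)$pattern_type,
               "II")
})

test_that("worsening one parameter never lowers the assigned severity", {
  # Pattern-type severity (I < II < III) is monotone in every parameter.
  # Points totals are monotone too, except when a worsening SPS crosses the
  # -10% shortcut: there the rubric stops scoring onset and PSI, so the
  # total resets to 4 while the type jumps straight to III.
  rub <- default_rubric()
  sev <- function(type) match(type, c("I", "II", "III"))
  score_of <- function(onset, sps, psi) {
    ps <- min(sps / (1 - psi / 100), sps)
    score_deformation(metrics_of(onset, ps, sps, psi), rub)
  }
  set.seed(99)
  for (i in 1:200) {
    onset <- runif(1, 0, 300)
    sps <- runif(1, -34, -2)
    psi <- runif(1, 0, 80)
    r0 <- score_of(onset, sps, psi)
    worsened <- list(
      score_of(onset + runif(1, 0, 200), sps, psi),
      score_of(onset, sps + runif(1, 0, 30), psi),
      score_of(onset, sps, psi + runif(1, 0, 50))
    )
    for (r1 in worsened) {
      expect_gte(sev(r1$pattern_type), sev(r0$pattern_type))
      if (r1$sps_shortcut == r0$sps_shortcut) {
        expect_gte(r1$points_total, r0$points_total)
      } else {
        expect_equal(r1$pattern_type, "III")
      }
    }
  }
})

test_that("analyze_curve classifies clean synthetic archetypes", {
  # an early-onset, deep-SPS, low-PSI curve is type I
  r1 <- analyze_curve(generate_curve(
    synthetic_spec("I", onset_true_ms = 45, sps_true_pct = -28,
                   psi_true_pct = 2, prestretch_amp_pct = 1)))
  expect_equal(r1$classification$pattern_type, "I")
  expect_equal(r1$classification$points_total, 0L)

  # SPS of -9 forces type III regardless of the other parameters
  r3 <- analyze_curve(generate_curve(
    synthetic_spec("III", onset_true_ms = 30, sps_true_pct = -9,
                   psi_true_pct = 5, prestretch_amp_pct = 1)))
  expect_equal(r3$classification$pattern_type, "III")
  expect_true(r3$classification$sps_shortcut)
})

test_that("shortcut consistency holds across random curves", {
  specs <- random_specs(120, noise_sd_pct = 0.15, seed = 31)
  for (spec in specs) {
    res <- analyze_curve(generate_curve(spec))
    m <- res$metrics
    expect_gte(m$systolic_peak_strain_pct, m$peak_strain_pct)
    if (m$peak_strain_pct < 0) expect_gte(m$psi_pct, 0)
    if (m$systolic_peak_strain_pct >= -10) {
      expect_equal(res$classification$pattern_type, "III")
    }
  }
})

test_that("malformed rubrics are rejected", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.yaml")
  writeLines(c("sps_shortcut_pct: -10",
               "onset_bands:",
               "  - {upper: 100, points: 0}",
               "  - {upper: 50, points: 1}"), bad)
  expect_error(read_rubric(bad), class = "rv_rubric_error")
  writeLines(c("onset_bands:",
               "  - {upper: .inf, points: 0}"), bad)
  expect_error(read_rubric(bad), class = "rv_rubric_error")
})
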