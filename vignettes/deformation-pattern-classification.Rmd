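---
title: "Classifying RV deformation patterns from longitudinal strain curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying RV deformation patterns from longitudinal strain curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvdeform)
```

## The measurement problem

Speckle-tracking echocardiography yields, per myocardial segment, a
longitudinal strain curve: percent length change over the cardiac cycle,
negative during shortening. In arrhythmogenic right ventricular
cardiomyopathy the basal RV free wall deforms abnormally early in the
disease, and the curve shape can be staged into three patterns: type I
(normal), type II (delayed onset of shortening, reduced systolic peak
strain, post-systolic shortening), and type III (severely reduced
systolic function, with most shortening after pulmonary valve closure).
Staging rests on four parameters — onset of shortening, peak strain (PS),
systolic peak strain (SPS) and the post-systolic index
(PSI = 100·(PS − SPS)/PS) — that are slow and observer-dependent to read
manually. `rvdeform` extracts them automatically and applies a
points-based classification.

## The pipeline and its assumptions

**Preprocessing.** Each curve is restricted to the window from QRS onset
(a manual annotation supplied with the data, not detected here) to the
last recorded sample, shifted so QRS onset is time zero, and linearly
interpolated onto a uniform 1000-sample grid. The fine common grid makes
onset times comparable across curves acquired at different framerates.
Linear interpolation is deliberate: it creates no extrema that are not in
the data, and the onset detector counts local maxima. Two further choices
are declared rather than forced by the method: samples before QRS onset
are discarded (the analysis windows all start there, and PS is defined on
the contraction–relaxation window), and strain values are *not* re-zeroed
at QRS onset, because the 1.5% peak-offset rule and the −10% cut-off are
absolute comparisons on the curve as drawn. Peak detection runs on the
interpolated grid, not the native one; on a linear interpolant the two
have the same local maxima (interpolation nodes), so the choice only
affects the time resolution at which the maxima are reported.

**Onset of shortening.** Mechanical shortening is assumed to start before
pulmonary valve closure (PVC), so only the segment strictly before PVC is
searched; a maximum exactly at PVC is excluded. A peak is a point larger
than both neighbours. A plateau — two or more equal values above both
flanks, which interpolating a flat native segment onto a finer grid
readily produces — counts once, at its first sample (the earliest
defensible onset). Selection walks the peaks in time order with a moving
candidate: if the next peak is more than 1.5% absolute strain below the
candidate ("more than" strict), the candidate is the onset; otherwise the
next peak becomes the candidate. We read the iteration as a pairwise
chain (candidate versus next) rather than always comparing against the
first peak, because the two-peak rule is stated symmetrically in
sequence; with two peaks the readings coincide. No prominence filter
suppresses micro-peaks: the rule defines none, so noise control is the
data's job (clinical curves are framerate-limited and tracker-smoothed;
the synthetic generator mirrors this by low-pass filtering its noise).
With no pre-PVC peak the onset falls back to 0 ms, i.e. QRS onset.

**Parameters.** PS is the global minimum of the prepared curve. SPS is
the minimum at or before PVC — inclusive, with the strain at PVC obtained
by interpolation when the grid does not land on it. An alternative
definition of SPS on the window from pulmonary valve *opening* to closure
exists in the field; the two differ only for curves dipping lowest before
valve opening, and this package uses the start-to-PVC window (PV opening
is carried as metadata only). PSI follows its formula, with PSI = 0 when
PS = SPS; PSI is undefined only when PS = 0 with SPS ≠ PS, which cannot
reach the scorer because such a curve triggers the −10% shortcut.

**Scoring.** The shortcut comes first: SPS ≥ −10% (inclusive, matching
"without a peak systolic strain below −10%") scores 4 points outright and
is type III; onset and PSI are then not scored and are reported as 0
points with a flag. Otherwise each of onset, PSI and SPS maps through
ordered bands to 0–2 points and the total maps to a type, with 4–6 points
always type III. The band cut-offs (onset ≤ 100/≤ 150/> 150 ms; PSI
≤ 10/≤ 25/> 25%; SPS ≤ −20/≤ −15/> −15%; totals 0 → I, 1–3 → II) are
package defaults shipped as YAML config rather than code, because only
the structure, the shortcut and the 4–6 → III rule are fixed by the
method; laboratories with their own calibration substitute a rubric file.
One consequence worth noting: pattern-type severity is monotone when any
single parameter worsens, but the points *total* is not across the
shortcut boundary — a 6-point curve whose SPS rises past −10% re-scores
to the flat 4 points, still type III.

## Tunable parameters

| Parameter | Unit | Default | Rationale |
|---|---|---|---|
| `n_samples` | samples | 1000 | uniform fine grid; ~0.8 ms resolution on an 800 ms cycle |
| `onset_threshold` | % strain | 1.5 | peak-offset rule of the onset detector |
| `sps_shortcut_pct` | % strain | −10 | severely reduced systolic function; fixed by the method |
| rubric bands | ms, % | see YAML | package defaults, reviewable config |
| `framerate_hz` (synth) | Hz | 75 | typical RV-focused acquisition; 1 frame ≈ 13.3 ms |
| `pvc_ms`, `cycle_ms` (synth) | ms | 350, 800 | plausible systole/cycle at resting heart rate |
| `noise_sd_pct` (synth) | % strain | 0 (cohorts: caller's choice) | smooth additive noise level |

## The synthetic generator

Ground-truth curves are built from piecewise half-cosine ramps: baseline
zero before QRS onset; an optional pre-stretch bump rising to its peak at
the true onset (types II/III; small for type I); a monotone descent
reaching SPS exactly at PVC; a post-systolic descent to PS (when
PSI > 0); recovery to baseline by end of cycle. Cosine ramps join with
zero slope, so the model has exactly one pre-PVC local maximum — at the
true onset — and the ground-truth peak structure is known by
construction. The model is sampled at the spec framerate and smooth noise
is added: white Gaussian noise filtered with a 5-sample Hann window and
rescaled to the requested SD, because raw white noise on a fine
interpolated grid would create spurious local maxima that
framerate-limited, tracker-smoothed clinical curves do not show.
Cohorts assign subjects to types by largest-remainder apportionment of
the mix proportions and draw parameters uniformly from per-type ranges
chosen to sit well inside the default rubric bands (`default_param_ranges()`),
so noise-free cohorts classify unambiguously.

What the generator does *not* emulate: drift and baseline wander,
beat-to-beat variability, tracking dropouts, multi-peak systolic
morphology beyond what noise induces, or any ECG waveform. Passing tests
on synthetic cohorts therefore demonstrate the algorithm's correctness
against its own definitions and its robustness to smooth noise — not
clinical agreement with human readers, which requires real annotated
curves. The agreement module exists precisely to run that comparison
(Bland–Altman, median/IQR of absolute differences, Spearman's ρ,
ICC(2,1) two-way random effects with absolute agreement and an F-based
confidence interval, and the fraction of differences within one native
time frame — computed per curve by default, with a flag for a global
frame duration). The time-frame statistic matters because the temporal
resolution floor of any onset comparison is one frame (1000/framerate
ms).

## Numerical choices and degenerate inputs

- Strict inequalities where the rules say "more than" (peak offset) and
  "below" (shortcut: SPS of exactly −10.0 triggers it).
- Ties on the interpolated grid are exact in floating point (linear
  interpolation between equal values reproduces the value), so plateau
  handling is deterministic.
- Curves with fewer than 3 native samples after QRS onset, non-monotone
  time axes, events outside the curve span, or non-numeric cells are
  rejected with classed errors naming the field.
- Synthetic specs are validated for internal consistency: PS ≤ SPS,
  PSI consistent with the PS/SPS pair to 0.1 PSI points, onset before
  PVC before end of cycle, and a positive pre-stretch bump whenever the
  true onset is positive (otherwise the onset is not marked on the curve
  and the ground truth would be meaningless).
- All randomness flows through explicit seeds; the generator restores
  the caller's RNG state.

## Validation scales

The test suite validates on synthetic data at the scales the package is
meant for: 1000-sample preprocessing on 100 random curves; brute-force
oracle equivalence of the peak detector and the full iterative rule on
1000 noisy curves; ground-truth recovery (onset within one 13.3 ms frame
in ≥ 99% of 500 noise-free curves at 75 Hz, PS/SPS within 0.5% strain)
and deterministic, 100%-correct classification of a 62-subject ×
3-segment (186-curve) noise-free cohort. Those sizes keep the whole
suite under half a minute while matching the cohort geometry the method
targets.

## Known limitations

- Classification is per curve; averaging parameters over a whole segment
  (a variant used in earlier staging work) is out of scope.
- QRS onset and valve timings are inputs; no ECG or Doppler processing.
- The default rubric bands are package defaults, not a clinically
  validated calibration; only the shortcut and the 4–6 → III mapping are
  fixed by the method.
- Vendor-proprietary exports and DICOM are not parsed; curves arrive as
  CSV.
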