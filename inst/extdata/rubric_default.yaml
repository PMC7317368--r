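# Points-based scoring rubric for RV deformation-pattern classification.
#
# Three parameters are scored: onset of shortening, post-systolic index,
# and systolic peak strain. Bands are ordered; a value v selects the first
# band with v <= upper. `.inf` marks the unbounded last band.
#
# Fixed rules (do not edit without revalidating the classifier):
#   - a systolic peak strain >= sps_shortcut_pct scores shortcut_points
#     outright and forces type III; onset and PSI are then not scored.
#   - totals of 4-6 points are type III.
# The remaining cut-offs are package defaults; laboratories applying their
# own calibration should substitute a rubric file via read_rubric().

sps_shortcut_pct: -10
shortcut_points: 4

onset_bands:            # onset of shortening, ms from QRS onset
  - {upper: 100, points: 0}
  - {upper: 150, points: 1}
  - {upper: .inf, points: 2}

psi_bands:              # post-systolic index, %
  - {upper: 10, points: 0}
  - {upper: 25, points: 1}
  - {upper: .inf, points: 2}

sps_bands:              # systolic peak strain, % (consulted only below the shortcut)
  - {upper: -20, points: 0}
  - {upper: -15, points: 1}
  - {upper: .inf, points: 2}

type_bands:             # total points -> deformation pattern type
  - {upper: 0, type: I}
  - {upper: 3, type: II}
  - {upper: 6, type: III}
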