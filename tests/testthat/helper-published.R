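# Published per-level summary statistics of the 555-patient reference cohort:
# used both as frozen expected values and as calibration targets.

# Per-level mean +/- SD of the manual canal area and each shape approximation
# (mm^2).
published_means <- tibble::tribble(
  ~level, ~manual_mean, ~manual_sd, ~ellipse_mean, ~ellipse_sd,
  ~triangle_mean, ~triangle_sd, ~rectangle_mean, ~rectangle_sd,
  "L1", 281.78, 48.89, 305.56, 56.50, 194.53, 35.97, 389.06, 71.93,
  "L2", 262.25, 49.79, 285.35, 57.05, 181.66, 36.32, 363.32, 72.64,
  "L3", 253.28, 49.93, 277.85, 58.15, 176.88, 37.02, 353.76, 74.04,
  "L4", 266.16, 64.16, 302.24, 75.08, 192.41, 47.80, 384.82, 95.60,
  "L5", 318.50, 90.23, 367.91, 100.59, 234.22, 64.03, 468.43, 128.07
)

# Per level x shape mean difference (estimate - manual, mm^2) and the shared
# per-level estimator-measurement correlation.
published_differences <- tibble::tribble(
  ~level, ~shape, ~md, ~r,
  "L1", "ellipse", 23.78, 0.907,
  "L1", "triangle", -87.25, 0.907,
  "L1", "rectangle", 107.28, 0.907,
  "L2", "ellipse", 23.10, 0.934,
  "L2", "triangle", -80.59, 0.934,
  "L2", "rectangle", 101.07, 0.934,
  "L3", "ellipse", 24.57, 0.909,
  "L3", "triangle", -76.40, 0.909,
  "L3", "rectangle", 100.48, 0.909,
  "L4", "ellipse", 36.08, 0.905,
  "L4", "triangle", -73.75, 0.905,
  "L4", "rectangle", 118.66, 0.905,
  "L5", "ellipse", 49.41, 0.931,
  "L5", "triangle", -84.28, 0.931,
  "L5", "rectangle", 149.93, 0.931
)

# Per level x shape aggregate percent error (%).
published_percent_errors <- tibble::tribble(
  ~level, ~ellipse, ~triangle, ~rectangle,
  "L1", 8.44, -30.96, 38.07,
  "L2", 8.81, -30.73, 38.54,
  "L3", 9.70, -30.16, 39.67,
  "L4", 13.56, -27.71, 44.58,
  "L5", 15.51, -26.46, 47.07
)
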