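# Per-level calibration targets for the synthetic cohort generator.
#
# manual_*  : mean/SD of the manually traced canal area (mm^2)
# product_* : mean/SD of the diameter product IPD x AP (mm^2); identical to
#             the rectangle-approximation moments
# target_r  : Pearson correlation between any shape approximation and the
#             manual area (shared by all three shapes at a level)
#
# Values are the published per-level summary statistics of a 555-patient
# young-adult (18-35 y) lumbar CT cohort. The IPD marginal is unreported
# there; ipd_mean / ipd_cv below are anatomically plausible defaults that
# only control how the product is split into IPD and AP.
defaults:
  ipd_mean: 24.0
  ipd_cv: 0.08
levels:
  L1: {manual_mean: 281.78, manual_sd: 48.89, product_mean: 389.06, product_sd: 71.93, target_r: 0.907}
  L2: {manual_mean: 262.25, manual_sd: 49.79, product_mean: 363.32, product_sd: 72.64, target_r: 0.934}
  L3: {manual_mean: 253.28, manual_sd: 49.93, product_mean: 353.76, product_sd: 74.04, target_r: 0.909}
  L4: {manual_mean: 266.16, manual_sd: 64.16, product_mean: 384.82, product_sd: 95.60, target_r: 0.905}
  L5: {manual_mean: 318.50, manual_sd: 90.23, product_mean: 468.43, product_sd: 128.07, target_r: 0.931}
# Cohort-level demographic moments (realism only; never used in statistics).
# Drawn independently, so bmi is not constrained to equal weight/height^2.
demographics:
  female_fraction: 0.5838
  age_years: {mean: 27.2, sd: 4.5, min: 18.0, max: 35.0}
  height_m: {mean: 1.54, sd: 0.09}
  weight_kg: {mean: 80.44, sd: 23.42}
  bmi: {mean: 28.27, sd: 7.2}
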