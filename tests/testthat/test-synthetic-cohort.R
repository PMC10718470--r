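test_that("calibration closed forms match hand-evaluated values", {
  cal <- calibrate_from_tables(281.78, 48.89, 389.06, 71.93, 0.907, level = "L1")
  expect_equal(cal$slope, 0.907 * 71.93 / 48.89)
  expect_equal(cal$slope, 1.3344, tolerance = 1e-4)
  expect_equal(cal$intercept, 13.0, tolerance = 0.01)
  expect_equal(cal$noise_sd, 30.29, tolerance = 0.01)
  # invariants tie the derived parameters back to the targets
  expect_equal(cal$intercept, cal$product_mean - cal$slope * cal$manual_mean)
  expect_equal(cal$noise_sd, cal$product_sd * sqrt(1 - cal$target_r^2))
})

test_that("calibration limits behave as the model predicts", {
  # r -> 1 with equal moments: identity link, no noise
  lim <- calibrate_from_tables(300, 50, 300, 50, 1 - 1e-12)
  expect_equal(lim$slope, 1, tolerance = 1e-9)
  expect_equal(lim$intercept, 0, tolerance = 1e-6)
  expect_equal(lim$noise_sd, 0, tolerance = 1e-3)
  # r = 0.5: noise carries sqrt(3)/2 of the product SD
  half <- calibrate_from_tables(300, 50, 380, 70, 0.5)
  expect_equal(half$noise_sd, 70 * sqrt(0.75))
})

test_that("invalid calibration inputs are rejected", {
  expect_error(calibrate_from_tables(300, 0, 380, 70, 0.9), "manual_sd")
  expect_error(calibrate_from_tables(300, 50, 380, -1, 0.9), "product_sd")
  expect_error(calibrate_from_tables(300, 50, 380, 70, 1), "target_r")
  expect_error(calibrate_from_tables(300, 50, 380, 70, -0.2), "target_r")
})

test_that("the packaged calibration file loads all five levels", {
  cal <- level_calibrations()
  expect_equal(cal$level, vertebral_levels())
  expect_equal(cal$manual_mean, published_means$manual_mean)
  expect_equal(cal$manual_sd, published_means$manual_sd)
  # product targets equal the rectangle-approximation moments
  expect_equal(cal$product_mean, published_means$rectangle_mean)
  expect_equal(cal$product_sd, published_means$rectangle_sd)
  expect_equal(cal$target_r,
               unique(published_differences[c("level", "r")])$r)
  expect_false(is.null(attr(cal, "demographics")))
})

test_that("generated cohorts are positive, exact-product, and reproducible", {
  spec <- cohort_spec(n_patients = 200, seed = 123)
  co <- generate_cohort(spec)
  expect_equal(nrow(co), 200 * 5)
  expect_true(all(co$ipd_mm > 0))
  expect_true(all(co$ap_mm > 0))
  expect_true(all(co$canal_area_mm2 > 0))
  expect_false(any(duplicated(co[c("patient_id", "level")])))
  # AP is defined as product / IPD, so the product round-trips exactly
  again <- generate_cohort(cohort_spec(n_patients = 200, seed = 123))
  expect_identical(co, again)
  other <- generate_cohort(cohort_spec(n_patients = 200, seed = 124))
  expect_false(identical(co, other))
})

test_that("n = 0 and level subsets behave", {
  empty <- generate_cohort(cohort_spec(n_patients = 0))
  expect_equal(nrow(empty), 0)
  expect_equal(names(empty),
               c("patient_id", "level", "ipd_mm", "ap_mm", "canal_area_mm2"))
  sub <- generate_cohort(cohort_spec(n_patients = 5, levels = c("L2", "L4")))
  expect_equal(sort(unique(sub$level)), c("L2", "L4"))
  expect_error(
    generate_cohort(cohort_spec(5, levels = "L3"),
                    calibrate_from_tables(300, 50, 380, 70, 0.9, level = "L1")),
    "no calibration available for level\\(s\\): L3"
  )
  expect_error(cohort_spec(-1), "nonnegative")
})

test_that("both positivity policies yield valid cohorts", {
  for (policy in c("resample", "reject")) {
    co <- generate_cohort(cohort_spec(50, levels = "L5", seed = 3,
                                      positivity_policy = policy))
    expect_true(all(co$canal_area_mm2 > 0 & co$ap_mm > 0 & co$ipd_mm > 0))
  }
})

test_that("split_product inverts the product exactly", {
  s <- split_product(389.06, 24)
  expect_equal(s$ap_mm, 389.06 / 24)
  expect_equal(s$ipd_mm * s$ap_mm, 389.06)
  sym <- split_product(400, sqrt(400))
  expect_equal(sym$ipd_mm, sym$ap_mm)
  expect_error(split_product(-1, 24), "product")
  expect_error(split_product(400, 0), "ipd")
})

test_that("sample moments and the IPD marginal track the calibration", {
  cal <- level_calibrations()
  co <- generate_cohort(cohort_spec(n_patients = 2e4, levels = "L1", seed = 5),
                        cal)
  l1 <- cal[cal$level == "L1", ]
  expect_equal(mean(co$canal_area_mm2), l1$manual_mean, tolerance = 0.01)
  expect_equal(stats::sd(co$canal_area_mm2), l1$manual_sd, tolerance = 0.02)
  prod <- co$ipd_mm * co$ap_mm
  expect_equal(mean(prod), l1$product_mean, tolerance = 0.01)
  expect_equal(stats::sd(prod), l1$product_sd, tolerance = 0.02)
  expect_equal(stats::cor(prod, co$canal_area_mm2), l1$target_r,
               tolerance = 0.02)
  # IPD split marginal: mean and CV within 2% of configuration
  expect_equal(mean(co$ipd_mm), l1$ipd_mean, tolerance = 0.02)
  expect_equal(stats::sd(co$ipd_mm) / mean(co$ipd_mm), l1$ipd_cv,
               tolerance = 0.02)
})

test_that("demographics are present, bounded, and statistics-free", {
  co <- generate_cohort(cohort_spec(n_patients = 300, seed = 9,
                                    demographics = TRUE))
  expect_true(all(c("sex", "age", "height", "weight", "bmi") %in% names(co)))
  expect_true(all(co$sex %in% c("M", "F")))
  expect_true(all(co$age > 18 & co$age < 35))
  expect_true(all(co$height > 0 & co$weight > 0 & co$bmi > 0))
  # each patient keeps one demographic row across levels
  one <- co[co$patient_id == co$patient_id[1], ]
  expect_equal(length(unique(one$height)), 1)
  # agreement statistics are identical with and without demographics
  plain <- generate_cohort(cohort_spec(n_patients = 300, seed = 9))
  expect_equal(evaluate_cohort(co), evaluate_cohort(plain))
})
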