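# Small deterministic measurement tables built in code for unit tests.

# Hand-sized cohort at one level with a known manual/product relationship.
toy_level <- function(n = 12, level = "L1", k = 0.72, noise = 0, seed = 99) {
  withr::with_seed(seed, {
    ipd <- seq(20, 28, length.out = n)
    ap <- seq(14, 19, length.out = n)
    product <- ipd * ap
    tibble::tibble(
      patient_id = sprintf("T%03d", seq_len(n)),
      level = level,
      ipd_mm = ipd,
      ap_mm = ap,
      canal_area_mm2 = k * product + if (noise > 0) stats::rnorm(n, 0, noise) else 0
    )
  })
}

# Random positive measurement table spanning several levels.
random_cohort <- function(n = 30, seed = 7) {
  withr::with_seed(seed, {
    lv <- sample(vertebral_levels(), n, replace = TRUE)
    tibble::tibble(
      patient_id = sprintf("R%03d", seq_len(n)),
      level = lv,
      ipd_mm = stats::runif(n, 18, 30),
      ap_mm = stats::runif(n, 12, 22),
      canal_area_mm2 = stats::runif(n, 180, 420)
    )
  })
}
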