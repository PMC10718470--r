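#' Specify a synthetic cohort
#'
#' Bundles the simulation settings consumed by [generate_cohort()].
#'
#' @param n_patients Number of patients (>= 0); each contributes one record
#'   per requested level.
#' @param levels Subset of [vertebral_levels()].
#' @param seed Integer seed; a fixed seed makes the generated table
#'   bit-reproducible.
#' @param positivity_policy How nonpositive draws are handled:
#'   `"resample"` (default) redraws only the offending variate;
#'   `"reject"` regenerates the whole record. Both error out after 1e6
#'   cumulative redraws (only reachable with pathological calibrations).
#' @param demographics If `TRUE`, attach per-patient sex, age, height,
#'   weight and BMI drawn independently at the calibration file's moments.
#'   Realism only; no statistic in the pipeline uses them.
#' @return A `cohort_spec` list.
#' @export
#' @examples
#' cohort_spec(n_patients = 555, seed = 42)
cohort_spec <- function(n_patients, levels = vertebral_levels(), seed = 1L,
                        positivity_policy = c("resample", "reject"),
                        demographics = FALSE) {
  positivity_policy <- match.arg(positivity_policy)
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 0L) {
    stop("`n_patients` must be a nonnegative integer", call. = FALSE)
  }
  check_level(levels)
  levels <- intersect(vertebral_levels(), unique(levels))
  structure(
    list(
      n_patients = n_patients,
      levels = levels,
      seed = as.integer(seed),
      positivity_policy = positivity_policy,
      demographics = isTRUE(demographics)
    ),
    class = "cohort_spec"
  )
}

#' Generate a moment-calibrated synthetic cohort
#'
#' For each requested level, draws the manual canal area A from a
#' truncated-at-zero normal at the calibrated moments, links the diameter
#' product P = IPD x AP to it through the calibrated regression
#' (P = slope * A + intercept + noise), draws the interpedicular distance
#' as an independent positive size variable, and sets AP = P / IPD so that
#' `ipd_mm * ap_mm` reproduces the product exactly. In expectation the
#' per-level sample (mean A, SD A, mean P, SD P, corr(P, A)) equal the
#' calibration targets; truncation distortion is negligible at the
#' calibrated coefficients of variation (< 0.3).
#'
#' @param spec A [cohort_spec()].
#' @param calibrations Per-level calibration tibble, as returned by
#'   [level_calibrations()] (the default) or built with
#'   [calibrate_from_tables()].
#' @return A long measurement tibble: `patient_id`, optional demographic
#'   columns (`sex`, `age`, `height`, `weight`, `bmi`), `level`, `ipd_mm`,
#'   `ap_mm`, `canal_area_mm2`; one row per patient x level, ordered by
#'   level then patient.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_patients = 10, seed = 1))
#' head(cohort)
generate_cohort <- function(spec, calibrations = level_calibrations()) {
  if (!inherits(spec, "cohort_spec")) {
    stop("`spec` must be built with cohort_spec()", call. = FALSE)
  }
  missing_levels <- setdiff(spec$levels, calibrations$level)
  if (length(missing_levels)) {
    stop(sprintf("no calibration available for level(s): %s",
                 paste(missing_levels, collapse = ", ")), call. = FALSE)
  }
  n <- spec$n_patients
  empty <- tibble(
    patient_id = character(), level = character(),
    ipd_mm = numeric(), ap_mm = numeric(), canal_area_mm2 = numeric()
  )
  if (n == 0L || length(spec$levels) == 0L) return(empty)

  withr::with_seed(spec$seed, {
    patient_id <- sprintf("P%05d", seq_len(n))
    per_level <- lapply(spec$levels, function(lv) {
      cal <- calibrations[calibrations$level == lv, ]
      m <- draw_level(n, cal, spec$positivity_policy)
      tibble(
        patient_id = patient_id,
        level = lv,
        ipd_mm = m$ipd,
        ap_mm = m$product / m$ipd,
        canal_area_mm2 = m$area
      )
    })
    # Demographics are drawn after the measurements so that toggling them
    # never changes the measurement stream for a given seed.
    demo <- if (spec$demographics) {
      draw_demographics(n, attr(calibrations, "demographics"))
    }
    if (!is.null(demo)) {
      per_level <- lapply(per_level, function(out) {
        dplyr::bind_cols(out[1], demo, out[-1])
      })
    }
    dplyr::bind_rows(per_level)
  })
}

# One level's raw draws: latent manual area, regression-linked product,
# independent IPD. Positivity enforced per `policy`; see cohort_spec().
draw_level <- function(n, cal, policy) {
  ipd_sd <- cal$ipd_mean * cal$ipd_cv
  area <- stats::rnorm(n, cal$manual_mean, cal$manual_sd)
  eps <- stats::rnorm(n, 0, cal$noise_sd)
  ipd <- stats::rnorm(n, cal$ipd_mean, ipd_sd)
  attempts <- 0L
  repeat {
    product <- cal$slope * area + cal$intercept + eps
    if (policy == "resample") {
      bad_a <- which(area <= 0)
      bad_e <- which(area > 0 & product <= 0)
      bad_i <- which(ipd <= 0)
      n_bad <- length(bad_a) + length(bad_e) + length(bad_i)
      if (n_bad == 0L) break
      attempts <- attempts + n_bad
      if (attempts > 1e6) {
        stop("positivity resampling exceeded 1e6 attempts; calibration places too much mass below zero",
             call. = FALSE)
      }
      area[bad_a] <- stats::rnorm(length(bad_a), cal$manual_mean, cal$manual_sd)
      eps[bad_e] <- stats::rnorm(length(bad_e), 0, cal$noise_sd)
      ipd[bad_i] <- stats::rnorm(length(bad_i), cal$ipd_mean, ipd_sd)
    } else {
      bad <- which(area <= 0 | product <= 0 | ipd <= 0)
      if (length(bad) == 0L) break
      attempts <- attempts + length(bad)
      if (attempts > 1e6) {
        stop("positivity rejection exceeded 1e6 attempts; calibration places too much mass below zero",
             call. = FALSE)
      }
      area[bad] <- stats::rnorm(length(bad), cal$manual_mean, cal$manual_sd)
      eps[bad] <- stats::rnorm(length(bad), 0, cal$noise_sd)
      ipd[bad] <- stats::rnorm(length(bad), cal$ipd_mean, ipd_sd)
    }
  }
  list(area = area, product = product, ipd = ipd)
}

# Independent truncated-normal demographics at configured moments.
draw_demographics <- function(n, demo_cfg) {
  cfg <- demo_cfg %||% list()
  female_fraction <- cfg$female_fraction %||% 0.5838
  age <- cfg$age_years %||% list(mean = 27.2, sd = 4.5, min = 18, max = 35)
  height <- cfg$height_m %||% list(mean = 1.54, sd = 0.09)
  weight <- cfg$weight_kg %||% list(mean = 80.44, sd = 23.42)
  bmi <- cfg$bmi %||% list(mean = 28.27, sd = 7.2)
  tibble(
    sex = ifelse(stats::runif(n) < female_fraction, "F", "M"),
    age = rnorm_bounded(n, age$mean, age$sd, age$min %||% 0, age$max %||% Inf),
    height = rnorm_bounded(n, height$mean, height$sd, 0, Inf),
    weight = rnorm_bounded(n, weight$mean, weight$sd, 0, Inf),
    bmi = rnorm_bounded(n, bmi$mean, bmi$sd, 0, Inf)
  )
}

rnorm_bounded <- function(n, mean, sd, lower, upper) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lower | x >= upper)
  attempts <- 0L
  while (length(bad)) {
    attempts <- attempts + length(bad)
    if (attempts > 1e6) stop("bounded resampling exceeded 1e6 attempts", call. = FALSE)
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x <= lower | x >= upper)
  }
  x
}

#' Split a diameter product into IPD and AP
#'
#' Given the product P = IPD x AP and an IPD value, recovers
#' AP = P / IPD so that the product is reproduced to machine precision.
#' The published summaries report only the product's moments, so the split
#' is a modeling convenience: it never changes the product, the area, or
#' any agreement statistic.
#'
#' @param product Diameter product in mm^2, > 0.
#' @param ipd Interpedicular distance in mm, > 0.
#' @return Tibble with columns `ipd_mm` and `ap_mm`.
#' @export
#' @examples
#' split_product(389.06, 24)
split_product <- function(product, ipd) {
  check_positive(product, "product")
  check_positive(ipd, "ipd")
  tibble(ipd_mm = ipd, ap_mm = product / ipd)
}
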