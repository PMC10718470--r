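#' Mean difference between paired estimates and measurements
#'
#' Mean and sample standard deviation (n - 1 denominator) of the paired
#' differences `estimate - manual`, the basic agreement summary for a
#' method-comparison study.
#'
#' @param estimate,manual Paired numeric vectors of areas in mm^2.
#' @return A named list with `md` (mean difference, mm^2) and `sd`
#'   (SD of the differences, mm^2).
#' @export
#' @examples
#' mean_difference(c(11, 22, 33), c(10, 20, 30))
mean_difference <- function(estimate, manual) {
  if (length(estimate) != length(manual)) {
    stop("`estimate` and `manual` must have the same length", call. = FALSE)
  }
  if (length(estimate) < 2L) {
    stop("at least 2 pairs are required (SD of differences undefined otherwise)",
         call. = FALSE)
  }
  d <- estimate - manual
  list(md = mean(d), sd = stats::sd(d))
}

#' Percent error of an approximation relative to the measured area
#'
#' The aggregate mode (the default) is the ratio-of-means convention,
#' `100 * (mean(estimate) - mean(manual)) / mean(manual)`, which is fully
#' determined by the two group means; the per-subject mode averages the
#' individual relative errors `100 * (estimate - manual) / manual` and will
#' generally differ on real data.
#'
#' @param estimate,manual Numeric vectors (or scalars, in aggregate mode,
#'   holding the two group means) of areas in mm^2.
#' @param mode `"aggregate"` (default) or `"per_subject"`.
#' @return Signed percent error (%).
#' @export
#' @examples
#' percent_error(305.56, 281.78) # aggregate, from two means
percent_error <- function(estimate, manual, mode = c("aggregate", "per_subject")) {
  mode <- match.arg(mode)
  if (mode == "aggregate") {
    mean_manual <- mean(manual)
    if (!is.finite(mean_manual) || mean_manual <= 0) {
      stop("`manual` must have a strictly positive mean", call. = FALSE)
    }
    100 * (mean(estimate) - mean_manual) / mean_manual
  } else {
    if (length(estimate) != length(manual)) {
      stop("`estimate` and `manual` must have the same length", call. = FALSE)
    }
    check_positive(manual, "manual")
    mean(100 * (estimate - manual) / manual)
  }
}

#' Paired t-test on a vector of differences
#'
#' Two-sided one-sample t-test of the paired differences against zero,
#' delegated to [stats::t.test()].
#'
#' @param differences Numeric vector of paired differences (mm^2), n >= 2,
#'   with nonzero variance.
#' @return A named list: `t_statistic`, `df`, `p_value`.
#' @export
paired_t <- function(differences) {
  if (length(differences) < 2L) {
    stop("at least 2 differences are required", call. = FALSE)
  }
  if (stats::sd(differences) == 0) {
    stop("differences have zero variance; the t statistic is undefined",
         call. = FALSE)
  }
  fit <- stats::t.test(differences, mu = 0, alternative = "two.sided")
  list(
    t_statistic = unname(fit$statistic),
    df = unname(fit$parameter),
    p_value = fit$p.value
  )
}

#' Pearson correlation between approximated and measured areas
#'
#' Plain product-moment correlation via [stats::cor()]. Because every shape
#' approximation is a positive multiple of IPD x AP, the correlation with
#' the measured area is identical across shapes; it is reported once per
#' level.
#'
#' @param x,y Numeric vectors, n >= 3, each with nonzero variance.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have the same length", call. = FALSE)
  }
  if (length(x) < 3L) {
    stop("at least 3 pairs are required for a correlation", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: an input series has zero variance", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Agreement statistics for one vertebral level and one shape
#'
#' Compares the chosen shape approximation against the manually measured
#' canal area over all records of a single level: group means and SDs, mean
#' difference +/- SD, paired t-test, percent error and Pearson correlation.
#'
#' @param measurements Measurement table (columns `patient_id`, `level`,
#'   `ipd_mm`, `ap_mm`, `canal_area_mm2`) holding a single level.
#' @param shape One of [canal_shapes()].
#' @param percent_error_mode Passed to [percent_error()].
#' @return One-row tibble with columns `level`, `shape`, `n`, `mean_manual`,
#'   `sd_manual`, `mean_estimate`, `sd_estimate`, `mean_difference`,
#'   `sd_difference`, `t_statistic`, `p_value`, `percent_error`, `pearson_r`.
#' @export
evaluate_level <- function(measurements, shape,
                           percent_error_mode = c("aggregate", "per_subject")) {
  percent_error_mode <- match.arg(percent_error_mode)
  check_measurements(measurements)
  shape <- match.arg(shape, canal_shapes())
  lv <- unique(as.character(measurements$level))
  if (length(lv) != 1L) {
    stop(sprintf("`measurements` must hold a single level; found: %s",
                 paste(lv, collapse = ", ")), call. = FALSE)
  }
  manual <- measurements$canal_area_mm2
  estimate <- approximate_area(measurements$ipd_mm, measurements$ap_mm, shape)
  md <- mean_difference(estimate, manual)
  tt <- paired_t(estimate - manual)
  tibble(
    level = lv,
    shape = shape,
    n = length(manual),
    mean_manual = mean(manual),
    sd_manual = stats::sd(manual),
    mean_estimate = mean(estimate),
    sd_estimate = stats::sd(estimate),
    mean_difference = md$md,
    sd_difference = md$sd,
    t_statistic = tt$t_statistic,
    p_value = tt$p_value,
    percent_error = percent_error(estimate, manual, percent_error_mode),
    pearson_r = pearson_r(estimate, manual)
  )
}

#' Agreement statistics for a whole cohort
#'
#' Runs [evaluate_level()] for every level present in the table and every
#' requested shape, in the fixed report order (L1 to L5; ellipse, triangle,
#' rectangle).
#'
#' @inheritParams evaluate_level
#' @param shapes Subset of [canal_shapes()].
#' @return Tibble with one row per level x shape.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_patients = 50, seed = 1))
#' evaluate_cohort(cohort)
evaluate_cohort <- function(measurements, shapes = canal_shapes(),
                            percent_error_mode = c("aggregate", "per_subject")) {
  percent_error_mode <- match.arg(percent_error_mode)
  check_measurements(measurements)
  shapes <- match.arg(shapes, canal_shapes(), several.ok = TRUE)
  levels_present <- intersect(vertebral_levels(), unique(measurements$level))
  rows <- lapply(levels_present, function(lv) {
    one <- measurements[measurements$level == lv, , drop = FALSE]
    dplyr::bind_rows(lapply(shapes, function(sh) {
      evaluate_level(one, sh, percent_error_mode)
    }))
  })
  dplyr::bind_rows(rows)
}
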