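#' Calibrate a per-level generative model from summary moments
#'
#' Builds the bivariate-normal generative model used by [generate_cohort()]
#' from five published summary statistics of one vertebral level: the mean
#' and SD of the manually measured canal area A, the mean and SD of the
#' diameter product P = IPD x AP (equal to the rectangle-approximation
#' moments), and the target Pearson correlation r between any shape
#' approximation and A.
#'
#' The manual area is the latent truth, A ~ Normal(manual_mean, manual_sd^2),
#' and the product is regression-linked to it,
#' P = slope * A + intercept + Normal(0, noise_sd^2), with
#' \deqn{slope = r \sigma_P / \sigma_A,\quad
#'       intercept = \mu_P - slope \cdot \mu_A,\quad
#'       noise\_sd = \sigma_P \sqrt{1 - r^2},}
#' so that the simulated (mean P, SD P, corr(P, A)) hit the targets exactly
#' in expectation. The reverse direction (independent noise on A given P)
#' cannot reproduce the published moments, because it would force
#' SD(A) >= slope-scaled SD(P).
#'
#' @param manual_mean,manual_sd Moments of the measured canal area (mm^2),
#'   SD > 0.
#' @param product_mean,product_sd Moments of IPD x AP (mm^2), SD > 0.
#' @param target_r Target estimator-measurement correlation, strictly in
#'   (0, 1).
#' @param level Optional level label ("L1".."L5").
#' @param ipd_mean,ipd_cv Mean (mm) and coefficient of variation of the
#'   interpedicular distance used to split the product into IPD and AP.
#'   These affect only the split, never the product, the area or any
#'   agreement statistic.
#' @return One-row tibble with the inputs plus `slope`, `intercept`,
#'   `noise_sd`.
#' @export
#' @examples
#' calibrate_from_tables(281.78, 48.89, 389.06, 71.93, 0.907, level = "L1")
calibrate_from_tables <- function(manual_mean, manual_sd, product_mean,
                                  product_sd, target_r, level = NA_character_,
                                  ipd_mean = 24, ipd_cv = 0.08) {
  check_positive(manual_mean, "manual_mean")
  check_positive(manual_sd, "manual_sd")
  check_positive(product_mean, "product_mean")
  check_positive(product_sd, "product_sd")
  check_positive(ipd_mean, "ipd_mean")
  check_positive(ipd_cv, "ipd_cv")
  if (!is.na(level)) check_level(level)
  if (!is.numeric(target_r) || target_r <= 0 || target_r >= 1) {
    stop("`target_r` must lie strictly in (0, 1)", call. = FALSE)
  }
  slope <- target_r * product_sd / manual_sd
  tibble(
    level = level,
    manual_mean = manual_mean,
    manual_sd = manual_sd,
    product_mean = product_mean,
    product_sd = product_sd,
    target_r = target_r,
    slope = slope,
    intercept = product_mean - slope * manual_mean,
    noise_sd = product_sd * sqrt(1 - target_r^2),
    ipd_mean = ipd_mean,
    ipd_cv = ipd_cv
  )
}

#' Load the packaged (or a user-supplied) per-level calibration file
#'
#' The package ships a human-editable YAML config preloaded with the
#' published per-level summary statistics of a 555-patient young-adult
#' lumbar CT cohort (manual canal area mean +/- SD, diameter-product mean
#' +/- SD, estimator-measurement correlation, for L1--L5), plus the
#' IPD-split and demographic defaults. This function reads such a file and
#' derives the generative parameters with [calibrate_from_tables()].
#'
#' @param path Path to a calibration YAML; `NULL` (default) loads the
#'   packaged file at
#'   `system.file("extdata", "level_calibration.yaml", package = "canalarea")`.
#' @return Tibble with one calibration row per level (see
#'   [calibrate_from_tables()]). The demographic moments are attached as the
#'   `"demographics"` attribute.
#' @export
#' @examples
#' level_calibrations()
level_calibrations <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "level_calibration.yaml",
                        package = "canalarea")
  }
  if (!file.exists(path)) {
    stop(sprintf("calibration file not found: %s", path), call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$levels) || !length(cfg$levels)) {
    stop("calibration file has no `levels` section", call. = FALSE)
  }
  ipd_mean <- cfg$defaults$ipd_mean %||% 24
  ipd_cv <- cfg$defaults$ipd_cv %||% 0.08
  out <- dplyr::bind_rows(lapply(names(cfg$levels), function(lv) {
    m <- cfg$levels[[lv]]
    needed <- c("manual_mean", "manual_sd", "product_mean", "product_sd",
                "target_r")
    missing_keys <- setdiff(needed, names(m))
    if (length(missing_keys)) {
      stop(sprintf("calibration for %s is missing: %s", lv,
                   paste(missing_keys, collapse = ", ")), call. = FALSE)
    }
    calibrate_from_tables(
      m$manual_mean, m$manual_sd, m$product_mean, m$product_sd, m$target_r,
      level = lv,
      ipd_mean = m$ipd_mean %||% ipd_mean,
      ipd_cv = m$ipd_cv %||% ipd_cv
    )
  }))
  attr(out, "demographics") <- cfg$demographics
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
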