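#' Fit the second-order scale factor
#'
#' The three shape approximations are all multiples of the diameter product
#' P = IPD x AP, so any linear combination of them collapses to k * P for a
#' single scalar k. The second-order approximation therefore has exactly one
#' effective degree of freedom, and it is fitted by least squares through
#' the origin:
#' \deqn{\hat k = \sum_i A_i P_i / \sum_i P_i^2,}
#' where A is the manually measured area.
#'
#' @param measurements Measurement table with `ipd_mm`, `ap_mm` and
#'   `canal_area_mm2` present; at least 2 rows.
#' @return The fitted dimensionless scale factor `k_hat`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_patients = 100, seed = 7))
#' fit_scale_factor(cohort[cohort$level == "L1", ])
fit_scale_factor <- function(measurements) {
  check_measurements(measurements)
  if (nrow(measurements) < 2L) {
    stop("at least 2 measurements are required to fit a scale factor",
         call. = FALSE)
  }
  p <- measurements$ipd_mm * measurements$ap_mm
  a <- measurements$canal_area_mm2
  ssq <- sum(p^2)
  if (ssq == 0) stop("degenerate input: all diameter products are zero", call. = FALSE)
  sum(a * p) / ssq
}

#' Express a scale factor as an ellipse/triangle convex combination
#'
#' Re-parameterises `k_hat` as the weights (w_e, w_t) of a combination of
#' the over-estimating ellipse (factor pi/4) and under-estimating triangle
#' (factor 1/2) under the constraint w_e + w_t = 1:
#' `w_e = (k_hat - 1/2) / (pi/4 - 1/2)`. Weights outside \[0, 1\] are legal
#' (the combination then extrapolates beyond the two shapes) and flagged.
#'
#' @param k_hat Dimensionless scale factor.
#' @return Named list: `ellipse_weight`, `triangle_weight`, `extrapolating`.
#' @export
#' @examples
#' weights_from_factor(pi / 4) # pure ellipse
weights_from_factor <- function(k_hat) {
  stopifnot(is.numeric(k_hat), length(k_hat) == 1L, is.finite(k_hat))
  w_e <- (k_hat - 1 / 2) / (pi / 4 - 1 / 2)
  list(
    ellipse_weight = w_e,
    triangle_weight = 1 - w_e,
    extrapolating = w_e < 0 || w_e > 1
  )
}

# RMSE of the rescaled-product estimator k * IPD * AP against the manual area.
scale_factor_rmse <- function(measurements, k) {
  p <- measurements$ipd_mm * measurements$ap_mm
  sqrt(mean((measurements$canal_area_mm2 - k * p)^2))
}

#' Cross-validated error of the fitted scale factor
#'
#' k-fold cross-validation: rows are shuffled deterministically from `seed`,
#' split into `folds` contiguous folds, the scale factor is refitted on each
#' training complement and the pooled held-out residuals give the CV RMSE.
#'
#' @inheritParams fit_scale_factor
#' @param folds Number of folds (>= 2, <= n).
#' @param seed Integer seed controlling the shuffle; fixed seed gives a
#'   bit-reproducible result.
#' @return Cross-validated RMSE in mm^2.
#' @export
cross_validate <- function(measurements, folds = 5L, seed = 1L) {
  check_measurements(measurements)
  n <- nrow(measurements)
  folds <- as.integer(folds)
  if (folds < 2L) stop("`folds` must be at least 2", call. = FALSE)
  if (n < folds) {
    stop(sprintf("n = %d rows cannot be split into %d folds", n, folds),
         call. = FALSE)
  }
  perm <- withr::with_seed(seed, sample.int(n))
  fold_id <- rep_len(seq_len(folds), n)[order(perm)]
  sq_err <- numeric(n)
  for (f in seq_len(folds)) {
    held <- fold_id == f
    k_f <- fit_scale_factor(measurements[!held, , drop = FALSE])
    p <- measurements$ipd_mm[held] * measurements$ap_mm[held]
    sq_err[held] <- (measurements$canal_area_mm2[held] - k_f * p)^2
  }
  sqrt(mean(sq_err))
}

#' Fit the second-order approximation per level (or pooled)
#'
#' For each vertebral level (default) or for the pooled table, fits the
#' scale factor, decomposes it into ellipse/triangle weights, and reports
#' training and cross-validated RMSE.
#'
#' @inheritParams cross_validate
#' @param per_level If `TRUE` (default) fit one factor per level; the
#'   effective manual-area-to-product ratio drifts across levels, so pooling
#'   blurs a real anatomical trend. If `FALSE`, a single pooled fit.
#' @return Tibble with columns `level`, `n`, `k_hat`, `ellipse_weight`,
#'   `triangle_weight`, `extrapolating`, `training_rmse`, `cv_rmse`,
#'   `cv_folds`. `level` is `"pooled"` when `per_level = FALSE`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_patients = 80, seed = 3))
#' fit_second_order(cohort)
fit_second_order <- function(measurements, per_level = TRUE, folds = 5L,
                             seed = 1L) {
  check_measurements(measurements)
  groups <- if (per_level) {
    lvs <- intersect(vertebral_levels(), unique(measurements$level))
    stats::setNames(lapply(lvs, function(lv) {
      measurements[measurements$level == lv, , drop = FALSE]
    }), lvs)
  } else {
    list(pooled = measurements)
  }
  dplyr::bind_rows(lapply(names(groups), function(nm) {
    g <- groups[[nm]]
    k_hat <- fit_scale_factor(g)
    w <- weights_from_factor(k_hat)
    tibble(
      level = nm,
      n = nrow(g),
      k_hat = k_hat,
      ellipse_weight = w$ellipse_weight,
      triangle_weight = w$triangle_weight,
      extrapolating = w$extrapolating,
      training_rmse = scale_factor_rmse(g, k_hat),
      cv_rmse = cross_validate(g, folds = folds, seed = seed),
      cv_folds = as.integer(folds)
    )
  }))
}

#' Serialise second-order fits to a keyed text file
#'
#' Writes one `key value` pair per line (`<level>.<field> <value>`), full
#' precision, readable back with [read_second_order()].
#'
#' @param fits Tibble from [fit_second_order()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_second_order <- function(fits, path) {
  fields <- c("n", "k_hat", "ellipse_weight", "triangle_weight",
              "training_rmse", "cv_rmse", "cv_folds")
  lines <- unlist(lapply(seq_len(nrow(fits)), function(i) {
    vapply(fields, function(f) {
      sprintf("%s.%s %s", fits$level[i], f,
              format(fits[[f]][i], digits = 17, scientific = FALSE))
    }, character(1))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_second_order
#' @return `read_second_order()` returns the fits tibble (without the
#'   `extrapolating` flag, which is recomputed from the weights).
#' @export
read_second_order <- function(path) {
  raw <- utils::read.table(path, col.names = c("key", "value"),
                           colClasses = c("character", "numeric"))
  parts <- strsplit(raw$key, ".", fixed = TRUE)
  d <- tibble(
    level = vapply(parts, `[`, character(1), 1L),
    field = vapply(parts, `[`, character(1), 2L),
    value = raw$value
  )
  wide <- tidyr_pivot(d)
  wide$n <- as.integer(wide$n)
  wide$cv_folds <- as.integer(wide$cv_folds)
  wide$extrapolating <- wide$ellipse_weight < 0 | wide$ellipse_weight > 1
  wide
}

# Minimal long-to-wide reshape (level, field, value) used by read_second_order.
tidyr_pivot <- function(d) {
  lvs <- unique(d$level)
  fields <- unique(d$field)
  out <- lapply(fields, function(f) {
    v <- d$value[d$field == f]
    names(v) <- d$level[d$field == f]
    unname(v[lvs])
  })
  names(out) <- fields
  tibble(level = lvs, !!!out)
}
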