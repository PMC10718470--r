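# Internal argument checks. Error messages always name the offending field so
# that failures surfaced through the CLI point at the input, not the code.

check_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x)) {
    stop(sprintf("`%s` must be numeric, got %s", name, class(x)[1]), call. = FALSE)
  }
  if (anyNA(x)) {
    stop(sprintf("`%s` contains missing values", name), call. = FALSE)
  }
  bad <- if (strict) x <= 0 else x < 0
  if (any(bad)) {
    stop(sprintf(
      "`%s` must be strictly positive; offending value(s): %s",
      name, paste(utils::head(x[bad], 3L), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(x)
}

check_level <- function(level) {
  bad <- setdiff(unique(as.character(level)), vertebral_levels())
  if (length(bad)) {
    stop(sprintf(
      "`level` must be one of %s; got: %s",
      paste(vertebral_levels(), collapse = ", "), paste(bad, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(level)
}

# Columns every measurement table must carry for analysis.
measurement_columns <- function() {
  c("patient_id", "level", "ipd_mm", "ap_mm", "canal_area_mm2")
}

check_measurements <- function(measurements, require_area = TRUE) {
  needed <- measurement_columns()
  if (!require_area) needed <- setdiff(needed, "canal_area_mm2")
  missing_cols <- setdiff(needed, names(measurements))
  if (length(missing_cols)) {
    stop(sprintf(
      "measurement table is missing column(s): %s",
      paste(missing_cols, collapse = ", ")
    ), call. = FALSE)
  }
  if (nrow(measurements) == 0L) {
    stop("measurement table is empty", call. = FALSE)
  }
  check_level(measurements$level)
  check_positive(measurements$ipd_mm, "ipd_mm")
  check_positive(measurements$ap_mm, "ap_mm")
  if (require_area) check_positive(measurements$canal_area_mm2, "canal_area_mm2")
  invisible(measurements)
}
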