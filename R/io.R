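#' Read a cohort measurement table from CSV
#'
#' Long format, one row per patient x level, comma-separated with a
#' mandatory header. Required columns: `patient_id`, `level`, `ipd_mm`,
#' `ap_mm`, `canal_area_mm2`; optional demographic columns (`sex`, `age`,
#' `height`, `weight`, `bmi`) are preserved. Validation errors name the
#' offending row and field.
#'
#' @param path Path to the CSV file.
#' @return A validated measurement tibble.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cohort file not found: %s", path), call. = FALSE)
  }
  d <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  missing_cols <- setdiff(measurement_columns(), names(d))
  if (length(missing_cols)) {
    stop(sprintf("cohort file %s is missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(d) == 0L) return(d)
  d$level <- as.character(d$level)
  d$patient_id <- as.character(d$patient_id)
  check_level(d$level)
  for (col in c("ipd_mm", "ap_mm", "canal_area_mm2")) {
    v <- d[[col]]
    if (!is.numeric(v)) {
      stop(sprintf("column `%s` is not numeric", col), call. = FALSE)
    }
    bad <- which(is.na(v) | v <= 0)
    if (length(bad)) {
      stop(sprintf(
        "row %d: field `%s` must be strictly positive (got %s)",
        bad[1], col, format(v[bad[1]])
      ), call. = FALSE)
    }
  }
  dup <- duplicated(d[c("patient_id", "level")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop(sprintf("row %d: duplicate (patient_id, level) pair (%s, %s)",
                 i, d$patient_id[i], d$level[i]), call. = FALSE)
  }
  d
}

#' Write a cohort measurement table to CSV
#'
#' Full floating-point precision (values survive a write/read round trip
#' exactly); rounding is applied only when rendering reports.
#'
#' @param cohort Measurement tibble (as from [generate_cohort()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      out[[col]] <- vapply(out[[col]], format, character(1),
                           digits = 17, scientific = FALSE)
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
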