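#' Build the study report
#'
#' Assembles the three summary tables of a method-comparison run — per-level
#' mean +/- SD of the manual measurement and each shape approximation,
#' per level x shape mean difference +/- SD with p-value and correlation,
#' and the per level x shape percent-error grid — plus an optional
#' second-order block. Layout is deterministic: levels L1 to L5, shapes in
#' ellipse / triangle / rectangle order.
#'
#' Rounding is display-only and mirrors conventional reporting precision:
#' areas and percents to 2 decimals, correlations to 3, p-values below
#' 0.001 rendered as `<0.001`.
#'
#' @param agreement Tibble from [evaluate_cohort()] covering at least one
#'   level.
#' @param fits Optional tibble from [fit_second_order()].
#' @return A `study_report` object; `print()` / `format()` render it as
#'   aligned text, [report_records()] flattens it to key-value records.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_patients = 60, seed = 2))
#' build_report(evaluate_cohort(cohort))
build_report <- function(agreement, fits = NULL) {
  if (is.null(agreement) || nrow(agreement) == 0L) {
    stop("`agreement` has no rows; run evaluate_cohort() first", call. = FALSE)
  }
  lvs <- intersect(vertebral_levels(), unique(agreement$level))
  shapes <- intersect(canal_shapes(), unique(agreement$shape))
  agreement <- agreement[order(match(agreement$level, vertebral_levels()),
                               match(agreement$shape, canal_shapes())), ]
  structure(
    list(agreement = agreement, fits = fits, levels = lvs, shapes = shapes),
    class = "study_report"
  )
}

fmt2 <- function(x) sprintf("%.2f", x)
fmt_r <- function(x) sprintf("%.3f", x)
fmt_p <- function(p) ifelse(p < 1e-3, "<0.001", sprintf("%.3f", p))
fmt_pm <- function(m, s) sprintf("%s±%s", fmt2(m), fmt2(s))

pad_table <- function(rows) {
  widths <- apply(nchar(rows), 2, max)
  apply(rows, 1, function(r) {
    paste(mapply(formatC, r, width = widths, flag = "-"), collapse = "  ")
  })
}

#' @export
format.study_report <- function(x, ...) {
  ag <- x$agreement
  lines <- character()

  # Block 1: per-level mean +/- SD of manual measurement and each shape.
  hdr <- c("Level", "Manual", tools_title(x$shapes))
  rows <- t(vapply(x$levels, function(lv) {
    one <- ag[ag$level == lv, ]
    c(lv, fmt_pm(one$mean_manual[1], one$sd_manual[1]),
      vapply(x$shapes, function(sh) {
        r <- one[one$shape == sh, ]
        fmt_pm(r$mean_estimate, r$sd_estimate)
      }, character(1)))
  }, character(2 + length(x$shapes))))
  lines <- c(lines, "Mean measurements (mm², mean±SD)",
             pad_table(rbind(hdr, rows)), "")

  # Block 2: mean differences with significance and correlation.
  hdr2 <- c("Level", "Shape", "Mean difference (mm²)", "p-Value",
            "Correlation (r)")
  rows2 <- t(apply(ag, 1, function(r) {
    c(r[["level"]], tools_title(r[["shape"]]),
      fmt_pm(as.numeric(r[["mean_difference"]]), as.numeric(r[["sd_difference"]])),
      fmt_p(as.numeric(r[["p_value"]])),
      fmt_r(as.numeric(r[["pearson_r"]])))
  }))
  lines <- c(lines, "Mean differences vs manual measurement",
             pad_table(rbind(hdr2, rows2)), "")

  # Block 3: percent-error grid.
  hdr3 <- c("Level", tools_title(x$shapes))
  rows3 <- t(vapply(x$levels, function(lv) {
    one <- ag[ag$level == lv, ]
    c(lv, vapply(x$shapes, function(sh) {
      paste0(fmt2(one$percent_error[one$shape == sh]), "%")
    }, character(1)))
  }, character(1 + length(x$shapes))))
  lines <- c(lines, "Percent error vs manual measurement",
             pad_table(rbind(hdr3, rows3)))

  if (!is.null(x$fits) && nrow(x$fits) > 0L) {
    hdr4 <- c("Level", "k_hat", "w_ellipse", "w_triangle", "RMSE", "CV RMSE")
    rows4 <- t(apply(x$fits, 1, function(r) {
      c(r[["level"]], fmt_r(as.numeric(r[["k_hat"]])),
        fmt_r(as.numeric(r[["ellipse_weight"]])),
        fmt_r(as.numeric(r[["triangle_weight"]])),
        fmt2(as.numeric(r[["training_rmse"]])),
        fmt2(as.numeric(r[["cv_rmse"]])))
    }))
    lines <- c(lines, "", "Second-order approximation (area ≈ k_hat · IPD · AP)",
               pad_table(rbind(hdr4, rows4)))
  }
  unname(lines)
}

tools_title <- function(s) {
  paste0(toupper(substring(s, 1, 1)), substring(s, 2))
}

#' @export
print.study_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Flatten a study report to machine-readable key-value records
#'
#' @param report A `study_report` from [build_report()].
#' @return Long tibble with columns `level`, `shape`, `metric`, `value`
#'   (full precision, no display rounding).
#' @export
report_records <- function(report) {
  stopifnot(inherits(report, "study_report"))
  ag <- report$agreement
  metrics <- setdiff(names(ag), c("level", "shape"))
  dplyr::bind_rows(lapply(seq_len(nrow(ag)), function(i) {
    tibble(
      level = ag$level[i], shape = ag$shape[i], metric = metrics,
      value = unname(vapply(metrics, function(m) as.numeric(ag[[m]][i]),
                            numeric(1)))
    )
  }))
}

#' Write a study report to a text file
#'
#' @param report A `study_report`.
#' @param path Output path for the aligned-text rendering.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  writeLines(format(report), path)
  invisible(path)
}
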