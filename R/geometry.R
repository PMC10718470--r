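#' Canal shapes and vertebral levels
#'
#' The three geometric models used to approximate the canal cross-section
#' from the interpedicular distance (IPD, the "width" of the canal) and the
#' anteroposterior (AP) diameter (its "depth"), and the five lumbar levels
#' the pipeline analyses.
#'
#' @return A character vector: `canal_shapes()` returns
#'   `c("ellipse", "triangle", "rectangle")` (the fixed shape order used in
#'   every report); `vertebral_levels()` returns `c("L1", ..., "L5")`.
#' @export
#' @examples
#' canal_shapes()
canal_shapes <- function() c("ellipse", "triangle", "rectangle")

#' @rdname canal_shapes
#' @export
vertebral_levels <- function() paste0("L", 1:5)

#' Dimensionless scale factor of a shape approximation
#'
#' Each approximation is a fixed multiple of the diameter product
#' IPD x AP: treating the two diameters as the axes of an ellipse gives
#' area \eqn{\pi (IPD/2)(AP/2) = (\pi/4) \cdot IPD \cdot AP}; a triangle with
#' base IPD and height AP gives \eqn{IPD \cdot AP / 2}; a bounding rectangle
#' gives \eqn{IPD \cdot AP}. The factor is the whole difference between the
#' three estimators, which is why they are perfectly collinear.
#'
#' @param shape Character vector with elements from [canal_shapes()].
#' @return Numeric vector of factors: `pi/4`, `1/2`, `1`.
#' @export
#' @examples
#' shape_factor("ellipse") # pi/4
shape_factor <- function(shape) {
  factors <- c(ellipse = pi / 4, triangle = 1 / 2, rectangle = 1)
  shape <- as.character(shape)
  unknown <- setdiff(unique(shape), names(factors))
  if (length(unknown)) {
    stop(sprintf(
      "unknown shape(s): %s (expected %s)",
      paste(unknown, collapse = ", "), paste(names(factors), collapse = ", ")
    ), call. = FALSE)
  }
  unname(factors[shape])
}

#' Approximate the canal area from two linear measurements
#'
#' @param ipd Interpedicular distance in mm (strictly positive).
#' @param ap Anteroposterior canal diameter in mm (strictly positive).
#' @param shape One of [canal_shapes()]; vectorised with recycling.
#' @return Approximated area in mm^2: `shape_factor(shape) * ipd * ap`.
#' @export
#' @examples
#' approximate_area(24, 16.2, "ellipse")
approximate_area <- function(ipd, ap, shape = canal_shapes()) {
  if (identical(shape, canal_shapes())) shape <- shape[1]
  check_positive(ipd, "ipd")
  check_positive(ap, "ap")
  shape_factor(shape) * ipd * ap
}
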