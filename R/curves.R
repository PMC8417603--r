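#' Lorenz curve of a unit distribution
#'
#' Components are sorted ascending by unit share; vertex j of the
#' polyline is (j/k, cumulative share of the j smallest components). The
#' curve runs from (0, 0) to (1, 1), lies on or below the diagonal line
#' of equality, and is piecewise linear between vertices. The area
#' between the diagonal and the curve, doubled, is the Gini index; the
#' maximum vertical gap is the Hoover index.
#'
#' @param d a [unit_distribution()].
#' @return An object of class `ineq_curve` with elements `x`, `y`
#'   (vertex coordinates), `kind = "lorenz"`, `ordering = "ascending"`
#'   and `k`.
#' @examples
#' lorenz_curve(unit_distribution(c(360, 250, 150)))$y
#' @export
lorenz_curve <- function(d) {
  d <- as_unit_distribution(d)
  p <- sort(unit_shares(d))
  structure(
    list(x = seq(0, d$k) / d$k, y = c(0, cumsum(p)),
         kind = "lorenz", ordering = "ascending", k = d$k),
    class = "ineq_curve"
  )
}

#' Concentration curve (descending rank order)
#'
#' The rank-based variant of the Lorenz curve used by the Rosenbluth
#' index: components are sorted *descending* by share and the x-axis
#' carries the component ranks 0..k rather than cumulative component
#' shares. The curve runs from (0, 0) to (k, 1) and lies on or above the
#' diagonal of the k-by-1 rectangle. The reciprocal of twice the area
#' above the curve is the Rosenbluth index.
#'
#' @param d a [unit_distribution()].
#' @return An `ineq_curve` with `kind = "concentration"`.
#' @export
concentration_curve <- function(d) {
  d <- as_unit_distribution(d)
  p <- sort(unit_shares(d), decreasing = TRUE)
  structure(
    list(x = seq(0, d$k), y = c(0, cumsum(p)),
         kind = "concentration", ordering = "descending", k = d$k),
    class = "ineq_curve"
  )
}

trapezoid_area <- function(x, y) {
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

#' Area between the line of equality and the Lorenz curve
#'
#' The gap area A in the Gini identity G = A/(A+B) = 2A, computed by the
#' trapezoid rule on the vertex polyline (exact for discrete data, since
#' the curve is piecewise linear). Lies in `[0, 0.5)`.
#'
#' @param curve an `ineq_curve` of kind `"lorenz"`.
#' @return The gap area, a scalar.
#' @export
lorenz_gap_area <- function(curve) {
  check_curve(curve, "lorenz")
  0.5 - trapezoid_area(curve$x, curve$y)
}

#' Maximum vertical gap below the line of equality
#'
#' The largest vertical distance between the Lorenz curve and the
#' diagonal, attained at a vertex; equals the Hoover index.
#'
#' @param curve an `ineq_curve` of kind `"lorenz"`.
#' @return The maximum gap, a scalar in `[0, 1)`.
#' @export
max_vertical_gap <- function(curve) {
  check_curve(curve, "lorenz")
  max(curve$x - curve$y)
}

#' Area above the concentration curve
#'
#' The area A between the descending-rank concentration polyline and the
#' top edge y = 1 over x in `[0, k]`; the Rosenbluth index is 1/(2A).
#' Ranges from 0.5 (maximum inequality: the triangle with corners (0,0),
#' (0,1), (1,1)) to k/2 (perfect equality).
#'
#' @param curve an `ineq_curve` of kind `"concentration"`.
#' @return The area above the curve, a scalar in `[0.5, k/2]`.
#' @export
concentration_area_above <- function(curve) {
  check_curve(curve, "concentration")
  curve$k - trapezoid_area(curve$x, curve$y)
}

check_curve <- function(curve, kind) {
  if (!inherits(curve, "ineq_curve")) {
    ineq_stop("expected an `ineq_curve` object", "ineq_argument_error")
  }
  if (curve$kind != kind) {
    ineq_stop(sprintf("expected a %s curve, got a %s curve", kind, curve$kind),
              "ineq_argument_error")
  }
  invisible(curve)
}

#' @export
print.ineq_curve <- function(x, ...) {
  cat(sprintf("%s curve (%s order): %d vertices, (%g, %g) to (%g, %g)\n",
              x$kind, x$ordering, length(x$x),
              x$x[1], x$y[1], x$x[length(x$x)], x$y[length(x$y)]))
  invisible(x)
}

#' Curve coordinates as a data frame
#'
#' Two columns `x`, `y`: the vertex coordinates, ready for export or
#' external plotting.
#'
#' @param x an `ineq_curve`.
#' @param ... unused.
#' @return A `data.frame`.
#' @export
as.data.frame.ineq_curve <- function(x, ...) {
  data.frame(x = x$x, y = x$y)
}

#' Plot a Lorenz or concentration curve
#'
#' Draws the polyline together with the line of equality and shades the
#' area between the two (the area that the Gini index, respectively the
#' Rosenbluth index, summarizes).
#'
#' @param x an `ineq_curve`.
#' @param shade logical; shade the gap area.
#' @param shade_col fill color of the gap area.
#' @param ... passed to [graphics::plot.default()].
#' @export
plot.ineq_curve <- function(x, shade = TRUE, shade_col = "#9ecae1", ...) {
  if (x$kind == "lorenz") {
    xlab <- "Cumulative component share"
    ylab <- "Cumulative unit share"
    diag_y <- x$x
  } else {
    xlab <- "Component rank"
    ylab <- "Cumulative unit share"
    diag_y <- x$x / x$k
  }
  graphics::plot(x$x, x$y, type = "n", xlab = xlab, ylab = ylab,
                 main = paste0(toupper(substring(x$kind, 1, 1)),
                               substring(x$kind, 2), " curve"), ...)
  if (shade) {
    graphics::polygon(c(x$x, rev(x$x)), c(x$y, rev(diag_y)),
                      col = shade_col, border = NA)
  }
  graphics::lines(x$x, diag_y, lty = 2)
  graphics::lines(x$x, x$y, lwd = 2)
  graphics::points(x$x, x$y, pch = 16, cex = 0.6)
  invisible(x)
}
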