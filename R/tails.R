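#' Tail share ratio
#'
#' The ratio of the unit share held by the top `top_frac` of components
#' to the share held by the bottom `bottom_frac`, the two tails of the
#' Lorenz curve. Shares are read off the component-sorted Lorenz
#' polyline with linear interpolation at the fractional cut points
#' 1 - `top_frac` and `bottom_frac`, which keeps the estimator
#' continuous when the cut does not fall on a component boundary. When k
#' is small relative to the tail fractions a caution is emitted — with
#' three components, "the richest 20%" is not a well-resolved notion.
#'
#' [palma_ratio()] is the top-10%/bottom-40% special case and
#' [s80_s20_ratio()] the top-20%/bottom-20% (quintile share) case; at
#' perfect equality they equal 0.25 and 1 respectively.
#'
#' @param d a metric [unit_distribution()].
#' @param top_frac fraction of components forming the top tail, in (0, 1).
#' @param bottom_frac fraction forming the bottom tail, in (0, 1).
#' @return The ratio (>= 0); `Inf` with a warning when the bottom tail
#'   holds no units.
#' @examples
#' palma_ratio(unit_distribution(rep(5, 10)))  # 0.25
#' @export
share_ratio <- function(d, top_frac, bottom_frac) {
  d <- as_unit_distribution(d)
  for (f in list(top_frac, bottom_frac)) {
    if (!is.numeric(f) || length(f) != 1L || is.na(f) || f <= 0 || f >= 1) {
      ineq_stop("tail fractions must be single numbers strictly between 0 and 1",
                "ineq_parameter_error")
    }
  }
  if (top_frac + bottom_frac > 1) {
    ineq_stop("top and bottom tails overlap (top_frac + bottom_frac > 1)",
              "ineq_parameter_error")
  }
  if (d$k < 1 / min(top_frac, bottom_frac)) {
    warning(sprintf("only %d components: tail shares at fractions %g/%g rest on heavy interpolation; interpret with caution",
                    d$k, top_frac, bottom_frac), call. = FALSE)
  }
  lc <- lorenz_curve(d)
  lz <- function(x) stats::approx(lc$x, lc$y, xout = x)$y
  bottom <- lz(bottom_frac)
  top <- 1 - lz(1 - top_frac)
  if (bottom <= 0) {
    warning("bottom tail holds no units; ratio is infinite", call. = FALSE)
    return(Inf)
  }
  top / bottom
}

#' @rdname share_ratio
#' @export
palma_ratio <- function(d) share_ratio(d, top_frac = 0.10, bottom_frac = 0.40)

#' @rdname share_ratio
#' @export
s80_s20_ratio <- function(d) share_ratio(d, top_frac = 0.20, bottom_frac = 0.20)

#' Percentile ratio
#'
#' The ratio of two quantiles of the unit values, e.g. P90:P10 (90th over
#' 10th percentile) or P50:P10 (median over 10th percentile). Quantiles
#' use linear interpolation between order statistics
#' ([stats::quantile()] type 7); the convention is recorded on the result
#' so values are reproducible across software.
#'
#' @param d a metric [unit_distribution()].
#' @param p_hi,p_lo percentile levels in (0, 100) with `p_lo < p_hi`.
#' @return The ratio, with attribute `quantile_type = 7`; `Inf` with a
#'   warning when the low quantile is 0.
#' @examples
#' p90_p10_ratio(unit_distribution(1:100))  # 90.1 / 10.9
#' @export
percentile_ratio <- function(d, p_hi, p_lo) {
  d <- as_unit_distribution(d)
  for (p in list(p_hi, p_lo)) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p >= 100) {
      ineq_stop("percentile levels must be single numbers strictly between 0 and 100",
                "ineq_parameter_error")
    }
  }
  if (p_lo >= p_hi) {
    ineq_stop("`p_lo` must be below `p_hi`", "ineq_parameter_error")
  }
  q <- stats::quantile(d$units, probs = c(p_lo, p_hi) / 100,
                       type = 7, names = FALSE)
  out <- if (q[1] <= 0) {
    warning("low quantile is 0; ratio is infinite", call. = FALSE)
    Inf
  } else {
    q[2] / q[1]
  }
  structure(out, quantile_type = 7L)
}

#' @rdname percentile_ratio
#' @export
p90_p10_ratio <- function(d) percentile_ratio(d, p_hi = 90, p_lo = 10)

#' @rdname percentile_ratio
#' @export
p50_p10_ratio <- function(d) percentile_ratio(d, p_hi = 50, p_lo = 10)
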