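#' Construct a unit distribution
#'
#' The central data structure of the package: a vector of non-negative
#' *units* held by *components*. For metric variables the components are
#' individuals and the units their raw values (scores, reaction times,
#' incomes); for categorical variables the components are the categories
#' and the units their counts. All inequality and concentration measures
#' in the package consume this object.
#'
#' Missing values are always dropped (with a message reporting how many).
#' Negative values are never meaningful for these measures; depending on
#' `negative_policy` they either abort construction (default, naming the
#' offending positions) or are removed with a warning. Zero-unit ("null")
#' components are retained here — individual measures decide whether to
#' ignore them (the Herfindahl-Hirschman and Shannon indices do; the
#' deviation-model indices do not).
#'
#' @param units numeric vector of non-negative values (counts for
#'   categorical variables, raw values for metric variables).
#' @param kind one of `"metric"`, `"categorical"`, `"ordinal"`; ordinal
#'   variables are treated as categorical (their ordering is ignored by
#'   every measure here).
#' @param labels optional character vector of component identifiers,
#'   recycled checks aside, same length as `units`.
#' @param na_policy how to treat missing values; only `"drop"` is
#'   supported.
#' @param negative_policy `"error"` (default) to refuse negative values,
#'   `"remove"` to drop them with a warning.
#' @return An object of class `unit_dist`: a list with elements `units`,
#'   `kind`, `labels`, `k` (number of components), `N` (total unit sum)
#'   and `mean_units` (N/k).
#' @examples
#' d <- unit_distribution(c(360, 250, 150))
#' d$N            # 760
#' unit_shares(d) # 0.4737 0.3289 0.1974
#' @seealso [unit_shares()], [distribution_table()], [lorenz_curve()]
#' @export
unit_distribution <- function(units,
                              kind = c("metric", "categorical", "ordinal"),
                              labels = NULL,
                              na_policy = "drop",
                              negative_policy = c("error", "remove")) {
  kind <- match.arg(kind)
  negative_policy <- match.arg(negative_policy)
  na_policy <- match.arg(na_policy, "drop")

  if (!is.numeric(units)) {
    ineq_stop("`units` must be numeric", "ineq_type_error")
  }
  units <- as.numeric(units)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != length(units)) {
      ineq_stop("`labels` must have the same length as `units`",
                "ineq_argument_error")
    }
  }

  is_na <- is.na(units)
  if (any(is_na)) {
    message(sum(is_na), " missing value(s) dropped")
    units <- units[!is_na]
    if (!is.null(labels)) labels <- labels[!is_na]
  }
  if (length(units) == 0L) {
    ineq_stop("no non-missing units supplied", "ineq_input_error")
  }

  neg <- which(units < 0)
  if (length(neg) > 0L) {
    if (negative_policy == "error") {
      ineq_stop(
        sprintf("negative unit value(s) at position(s) %s; units must be non-negative (use negative_policy = \"remove\" to drop them)",
                paste(neg, collapse = ", ")),
        "ineq_negative_error"
      )
    }
    warning(length(neg), " negative value(s) removed", call. = FALSE)
    units <- units[-neg]
    if (!is.null(labels)) labels <- labels[-neg]
  }
  if (length(units) == 0L) {
    ineq_stop("no units remain after removing negatives", "ineq_input_error")
  }

  N <- sum(units)
  if (N <= 0) {
    ineq_stop("total unit sum must be positive", "ineq_input_error")
  }

  structure(
    list(units = units, kind = kind, labels = labels,
         k = length(units), N = N, mean_units = N / length(units)),
    class = "unit_dist"
  )
}

#' Test for / coerce to a unit distribution
#'
#' `as_unit_distribution()` passes `unit_dist` objects through unchanged
#' and otherwise constructs one from a numeric vector with the default
#' policies.
#'
#' @param x an object.
#' @param ... passed to [unit_distribution()] on coercion.
#' @return `is_unit_distribution()` a logical; `as_unit_distribution()` a
#'   `unit_dist`.
#' @export
is_unit_distribution <- function(x) inherits(x, "unit_dist")

#' @rdname is_unit_distribution
#' @export
as_unit_distribution <- function(x, ...) {
  if (is_unit_distribution(x)) x else unit_distribution(x, ...)
}

#' Unit shares of a distribution
#'
#' The unit share of component i is p_i = n_i / N, its fraction of the
#' total unit sum. Shares always sum to one.
#'
#' @param d a [unit_distribution()].
#' @return Numeric vector of shares in `[0, 1]`, same order as the input
#'   units.
#' @export
unit_shares <- function(d) {
  d <- as_unit_distribution(d)
  d$units / d$N
}

#' Per-component distribution table
#'
#' The five-column summary of the unit distribution: the values sorted
#' ascending, each component's unit share, the cumulative unit share, the
#' component share (1/k per row) and the cumulative component share — all
#' percentages on the 0–100 scale. The cumulative unit-share column equals
#' the Lorenz curve ordinates (times 100) at the component boundaries.
#'
#' @param d a [unit_distribution()].
#' @return A `data.frame` with columns `value`, `unit_share`,
#'   `cum_unit_share`, `component_share`, `cum_component_share`.
#' @examples
#' distribution_table(unit_distribution(c(360, 250, 150)))
#' @export
distribution_table <- function(d) {
  d <- as_unit_distribution(d)
  ord <- order(d$units)         # stable: ties keep input order
  v <- d$units[ord]
  us <- 100 * v / d$N
  cs <- rep(100 / d$k, d$k)
  data.frame(
    value = v,
    unit_share = us,
    cum_unit_share = cumsum(us),
    component_share = cs,
    cum_component_share = cumsum(cs),
    row.names = NULL
  )
}

#' Merge components into aliquot parts for plotting
#'
#' When a distribution has many components, plots become unreadable; the
#' components are then merged into `parts` aliquot (equal-sized) slices of
#' the ascending-sorted distribution, each slice holding exactly
#' `k/parts` component-equivalents. When `k` is not divisible by `parts`,
#' boundary components are split proportionally so the slices stay exactly
#' aliquot; the total unit sum is preserved. Distributions with `k <=
#' parts` are returned unchanged.
#'
#' This is a display transformation only: every measure must be computed
#' on the unmerged distribution.
#'
#' @param d a [unit_distribution()].
#' @param parts number of aliquot slices (default 20, i.e. 5% each).
#' @return A `unit_dist` with `min(k, parts)` components.
#' @export
merge_to_aliquots <- function(d, parts = 20L) {
  d <- as_unit_distribution(d)
  if (length(parts) != 1L || is.na(parts) || parts < 1) {
    ineq_stop("`parts` must be a positive integer", "ineq_argument_error")
  }
  parts <- as.integer(parts)
  if (d$k <= parts) {
    return(d)
  }
  s <- sort(d$units)
  cs <- c(0, cumsum(s))
  # cumulative units of the "first t components", fractional t interpolating
  # within the boundary component
  cum_at <- function(t) {
    f <- floor(t)
    frac <- t - f
    extra <- ifelse(frac > 0, frac * s[pmin(f + 1, d$k)], 0)
    cs[f + 1] + extra
  }
  bounds <- cum_at(seq_len(parts) * d$k / parts)
  merged <- diff(c(0, bounds))
  merged[parts] <- d$N - sum(merged[-parts])  # conserve N exactly
  unit_distribution(merged, kind = d$kind)
}

#' @export
print.unit_dist <- function(x, ...) {
  cat(sprintf("Unit distribution (%s): k = %d components, N = %g units\n",
              x$kind, x$k, x$N))
  u <- x$units
  shown <- if (x$k > 10) paste(c(format(u[1:10]), "..."), collapse = " ")
           else paste(format(u), collapse = " ")
  cat("  units:", shown, "\n")
  invisible(x)
}

#' Summarize a unit distribution
#'
#' Prints the component count, total, mean units and a compact set of
#' headline measures (Gini, corrected Gini, Hoover, Rosenbluth,
#' Herfindahl-Hirschman).
#'
#' @param object a `unit_dist`.
#' @param ... unused.
#' @export
summary.unit_dist <- function(object, ...) {
  out <- list(
    k = object$k, N = object$N, mean_units = object$mean_units,
    gini = gini(object),
    gini_corrected = if (object$k >= 2) gini_corrected(object) else NA_real_,
    hoover = hoover(object),
    rosenbluth = rosenbluth(object),
    hhi = hhi(object)
  )
  class(out) <- "summary.unit_dist"
  out
}

#' @export
print.summary.unit_dist <- function(x, ...) {
  cat(sprintf("k = %d, N = %g, mean units = %g\n", x$k, x$N, x$mean_units))
  cat(sprintf("Gini %.5f | corrected Gini %s | Hoover %.5f | Rosenbluth %.5f | HHI %.5f\n",
              x$gini,
              if (is.na(x$gini_corrected)) "NA" else sprintf("%.5f", x$gini_corrected),
              x$hoover, x$rosenbluth, x$hhi))
  invisible(x)
}

#' Plot a unit distribution as its Lorenz curve
#'
#' Draws the Lorenz curve with the line of equality and shades the gap
#' area whose doubled value is the Gini index. Distributions with more
#' than `merge_parts` components are merged into aliquot parts for
#' display only.
#'
#' @param x a `unit_dist`.
#' @param merge_parts aliquot parts used for display when k is large.
#' @param ... passed to [plot.ineq_curve()].
#' @export
plot.unit_dist <- function(x, merge_parts = 20L, ...) {
  dd <- merge_to_aliquots(x, merge_parts)
  plot(lorenz_curve(dd), ...)
}

# classified conditions so callers (and the CLI) can map error kinds
ineq_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "ineq_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
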