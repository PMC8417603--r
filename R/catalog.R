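# Static measure catalog: one row per measure, with polarity, admissible
# scale levels, model family, synonyms and limit rules. The limits are
# functions of k (components) and k' (non-null components) and are
# instantiated per dataset by measure_limits().

catalog_data <- function() {
  e <- function(...) c(...)
  rows <- list(
    list("gini", "Gini index", "deviations", "inequality",
         "categorical, metric", "",
         "0", "1 - 1/k"),
    list("gini_corrected", "Corrected Gini index", "deviations", "inequality",
         "categorical, metric", "",
         "0", "1"),
    list("hoover", "Hoover index", "deviations", "inequality",
         "categorical, metric", "Pietra index; Robin-Hood index; Schutz index",
         "0", "1 - 1/k"),
    list("hoover_corrected", "Corrected Hoover index", "deviations", "inequality",
         "categorical, metric", "",
         "0", "1"),
    list("rosenbluth", "Rosenbluth index", "deviations", "inequality",
         "categorical, metric", "Hall-Tideman index",
         "1/k", "1"),
    list("hhi", "Herfindahl-Hirschman index", "combinatorics", "inequality",
         "categorical, metric", "Herfindahl index; Hirschman index",
         "1/k'", "1"),
    list("simpson", "Simpson index", "combinatorics", "inequality",
         "categorical", "Simpson's D",
         "0", "1"),
    list("gini_simpson", "Gini-Simpson index", "combinatorics", "equality",
         "categorical",
         "Blau index; Hunter-Gaston discriminatory index; Gibbs-Martin index; probability of interspecific encounter",
         "0", "1"),
    list("inverse_simpson", "Inverse Simpson index", "combinatorics", "equality",
         "categorical", "",
         "1", "Inf"),
    list("shannon", "Shannon index", "entropy", "equality",
         "categorical", "Shannon-Weaver index; Shannon-Wiener index",
         "0", "log_a(k')"),
    list("generalized_entropy", "Generalized entropy index", "entropy", "inequality",
         "metric", "",
         "0", "Inf"),
    list("atkinson", "Atkinson index", "social welfare", "inequality",
         "metric", "",
         "0", "1"),
    list("palma", "Palma ratio", "tail ratio", "inequality",
         "metric", "",
         "1/4", "Inf"),
    list("s80_s20", "S80:S20 ratio", "tail ratio", "inequality",
         "metric", "20:20 ratio; quintile share ratio",
         "1", "Inf"),
    list("p90_p10", "P90:P10 ratio", "tail ratio", "inequality",
         "metric", "",
         "1", "Inf"),
    list("p50_p10", "P50:P10 ratio", "tail ratio", "inequality",
         "metric", "",
         "1", "Inf")
  )
  do.call(rbind, lapply(rows, function(r) {
    data.frame(id = r[[1]], name = r[[2]], model = r[[3]], polarity = r[[4]],
               scale_levels = r[[5]], synonyms = r[[6]],
               lower_limit = r[[7]], upper_limit = r[[8]],
               stringsAsFactors = FALSE)
  }))
}

#' Catalog of the implemented inequality measures
#'
#' One row per measure: identifier, canonical name, underlying model
#' family (deviations, combinatorics, entropy, social welfare, tail
#' ratio), polarity (whether the measure grows with inequality or with
#' equality/diversity), admissible scale levels, common synonyms, and
#' the theoretical lower/upper limits as formulas in k (number of
#' components) and k' (non-null components).
#'
#' @return A 16-row `data.frame`.
#' @seealso [measure_limits()], [measures_report()]
#' @export
measure_catalog <- function() {
  catalog_data()
}

#' Theoretical limits of a measure for given k
#'
#' Instantiates the catalog's limit formulas at a concrete number of
#' components.
#'
#' @param id a measure identifier from [measure_catalog()].
#' @param k number of components.
#' @param k_nonnull number of non-null components (defaults to `k`).
#' @param log_base logarithm base for the Shannon upper limit.
#' @return Named numeric vector `c(lower, upper)`; `upper` may be `Inf`.
#' @export
measure_limits <- function(id, k, k_nonnull = k, log_base = 2) {
  lims <- switch(
    id,
    gini = ,
    hoover = c(0, 1 - 1 / k),
    gini_corrected = ,
    hoover_corrected = c(0, 1),
    rosenbluth = c(1 / k, 1),
    hhi = c(1 / k_nonnull, 1),
    simpson = ,
    gini_simpson = c(0, 1),
    inverse_simpson = c(1, Inf),
    shannon = c(0, log(k_nonnull) / log(resolve_log_base(log_base))),
    generalized_entropy = c(0, Inf),
    atkinson = c(0, 1),
    palma = c(0.25, Inf),
    s80_s20 = ,
    p90_p10 = ,
    p50_p10 = c(1, Inf),
    ineq_stop(sprintf("unknown measure id \"%s\"", id), "ineq_parameter_error")
  )
  names(lims) <- c("lower", "upper")
  lims
}

#' Compute a table of inequality measures
#'
#' The package's central report: one row per requested measure with its
#' polarity, admissible scale levels, theoretical limits instantiated at
#' the data's k, and the computed value. Parameterized measures require
#' their parameter: `alpha` for the generalized entropy index, `epsilon`
#' for the Atkinson index — requesting them without one is an error. A
#' measure that is inapplicable to the data at hand (e.g. the Simpson
#' index on non-integer values) yields an `NA` value and a note in its
#' row; the rest of the report is unaffected.
#'
#' @param d a [unit_distribution()].
#' @param measures character vector of measure ids (default: all 16,
#'   with parameterized ones included only when their parameter is
#'   given).
#' @param alpha generalized entropy parameter.
#' @param epsilon Atkinson inequality-aversion parameter.
#' @param log_base Shannon logarithm base (default 2).
#' @return A `data.frame` of class `ineq_report` with columns `measure`,
#'   `name`, `polarity`, `scale_levels`, `lower`, `upper`, `value`
#'   (full precision) and `note`. The print method rounds values to 5
#'   decimal places.
#' @examples
#' measures_report(unit_distribution(c(360, 250, 150)),
#'                 c("gini", "hoover", "rosenbluth", "hhi"))
#' @export
measures_report <- function(d, measures = NULL, alpha = NULL, epsilon = NULL,
                            log_base = 2) {
  d <- as_unit_distribution(d)
  cat_df <- catalog_data()
  if (is.null(measures)) {
    measures <- cat_df$id
    if (is.null(alpha)) measures <- setdiff(measures, "generalized_entropy")
    if (is.null(epsilon)) measures <- setdiff(measures, "atkinson")
  }
  unknown <- setdiff(measures, cat_df$id)
  if (length(unknown) > 0) {
    ineq_stop(sprintf("unknown measure(s): %s (see measure_catalog())",
                      paste(unknown, collapse = ", ")),
              "ineq_parameter_error")
  }
  if ("generalized_entropy" %in% measures && is.null(alpha)) {
    ineq_stop("the generalized entropy index requires `alpha`",
              "ineq_parameter_error")
  }
  if ("atkinson" %in% measures && is.null(epsilon)) {
    ineq_stop("the Atkinson index requires `epsilon`",
              "ineq_parameter_error")
  }
  k_nonnull <- sum(d$units > 0)

  one <- function(id) {
    meta <- cat_df[cat_df$id == id, ]
    lims <- measure_limits(id, d$k, k_nonnull, log_base)
    val <- NA_real_
    note <- ""
    res <- tryCatch(
      switch(id,
             gini = gini(d),
             gini_corrected = gini_corrected(d),
             hoover = hoover(d),
             hoover_corrected = hoover_corrected(d),
             rosenbluth = rosenbluth(d),
             hhi = suppressMessages(hhi(d)),
             simpson = simpson(d),
             gini_simpson = gini_simpson(d),
             inverse_simpson = inverse_simpson(d),
             shannon = shannon(d, base = log_base),
             generalized_entropy = generalized_entropy(d, alpha),
             atkinson = atkinson(d, epsilon),
             palma = suppressWarnings(palma_ratio(d)),
             s80_s20 = suppressWarnings(s80_s20_ratio(d)),
             p90_p10 = suppressWarnings(p90_p10_ratio(d)),
             p50_p10 = suppressWarnings(p50_p10_ratio(d))),
      ineq_error = function(e) e
    )
    if (inherits(res, "condition")) {
      note <- conditionMessage(res)
    } else {
      val <- as.numeric(res)
    }
    data.frame(measure = id, name = meta$name, polarity = meta$polarity,
               scale_levels = meta$scale_levels,
               lower = lims[["lower"]], upper = lims[["upper"]],
               value = val, note = note, stringsAsFactors = FALSE)
  }

  out <- do.call(rbind, lapply(measures, one))
  rownames(out) <- NULL
  attr(out, "k") <- d$k
  attr(out, "N") <- d$N
  class(out) <- c("ineq_report", "data.frame")
  out
}

#' @export
print.ineq_report <- function(x, digits = 5, ...) {
  cat(sprintf("Inequality measures (k = %d, N = %g)\n",
              attr(x, "k"), attr(x, "N")))
  disp <- data.frame(
    measure = x$name,
    polarity = x$polarity,
    lower = formatC(x$lower, format = "f", digits = digits),
    upper = ifelse(is.finite(x$upper),
                   formatC(x$upper, format = "f", digits = digits), "Inf"),
    value = ifelse(is.na(x$value), "--",
                   ifelse(is.finite(x$value),
                          formatC(x$value, format = "f", digits = digits),
                          "Inf"))
  )
  print(disp, row.names = FALSE)
  bad <- nzchar(x$note)
  if (any(bad)) {
    cat("Notes:\n")
    for (i in which(bad)) cat("  -", x$measure[i], ":", x$note[i], "\n")
  }
  invisible(x)
}
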