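#' Read a numeric column from a delimited text file
#'
#' Parses a CSV-dialect file (configurable separator, optional header)
#' and turns one column into a [unit_distribution()]. Missing values are
#' dropped with a message reporting the count; negative values follow
#' `negative_policy` (refuse by default, or remove with a warning).
#'
#' @param path path to a delimited text file.
#' @param column column name (when `header = TRUE`) or 1-based index.
#' @param sep field separator (default `","`).
#' @param header does the file have a header row (default `TRUE`).
#' @param kind variable kind passed to [unit_distribution()].
#' @param negative_policy `"error"` or `"remove"`.
#' @return A `unit_dist`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("x", "1", "2", "3"), f)
#' read_column(f, "x")
#' @export
read_column <- function(path, column = 1L, sep = ",", header = TRUE,
                        kind = "metric", negative_policy = "error") {
  if (!file.exists(path)) {
    ineq_stop(sprintf("file not found: %s", path), "ineq_input_error")
  }
  df <- tryCatch(
    utils::read.table(path, sep = sep, header = header,
                      stringsAsFactors = FALSE, na.strings = c("NA", ""),
                      check.names = FALSE),
    error = function(e) {
      ineq_stop(sprintf("could not parse %s: %s", path, conditionMessage(e)),
                "ineq_input_error")
    }
  )
  if (is.character(column)) {
    if (!column %in% names(df)) {
      ineq_stop(sprintf("column \"%s\" not found; available columns: %s",
                        column, paste(names(df), collapse = ", ")),
                "ineq_input_error")
    }
    x <- df[[column]]
  } else {
    column <- as.integer(column)
    if (is.na(column) || column < 1L || column > ncol(df)) {
      ineq_stop(sprintf("column index %s out of range; the file has %d column(s): %s",
                        column, ncol(df), paste(names(df), collapse = ", ")),
                "ineq_input_error")
    }
    x <- df[[column]]
  }
  if (!is.numeric(x)) {
    xt <- suppressWarnings(as.numeric(x))
    if (all(is.na(xt) & !is.na(x))) {
      ineq_stop("selected column is not numeric", "ineq_input_error")
    }
    made_na <- sum(is.na(xt) & !is.na(x))
    if (made_na > 0) {
      ineq_stop(sprintf("selected column contains %d non-numeric entr%s; data need to be in a numerical format",
                        made_na, if (made_na == 1) "y" else "ies"),
                "ineq_input_error")
    }
    x <- xt
  }
  unit_distribution(x, kind = kind, negative_policy = negative_policy)
}

#' Export curve coordinates (and optionally a plot)
#'
#' Writes the vertex coordinates of the Lorenz or concentration curve as
#' two-column delimited text, and optionally renders the curve to a PNG.
#' Mirroring the display convention, the *plotted/exported polyline* is
#' aliquot-merged to at most `merge_parts` slices when the distribution
#' has more components than that (so a k = 100 input yields a 21-vertex
#' polyline); index computations must always use the unmerged data.
#'
#' @param d a [unit_distribution()].
#' @param which `"lorenz"` or `"concentration"`.
#' @param path output path for the coordinate CSV.
#' @param png_path optional output path for a rendered PNG.
#' @param merge_parts aliquot parts for display (default 20).
#' @param sep field separator for the coordinate file.
#' @return Invisibly, the exported `ineq_curve`.
#' @export
export_curve <- function(d, which = c("lorenz", "concentration"), path,
                         png_path = NULL, merge_parts = 20L, sep = ",") {
  d <- as_unit_distribution(d)
  which <- match.arg(which)
  dd <- merge_to_aliquots(d, merge_parts)
  curve <- if (which == "lorenz") lorenz_curve(dd) else concentration_curve(dd)
  ok <- tryCatch({
    utils::write.table(as.data.frame(curve), path, sep = sep,
                       row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    ineq_stop(sprintf("could not write %s: %s", path, conditionMessage(ok)),
              "ineq_output_error")
  }
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 640, height = 640)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot(curve)
  }
  invisible(curve)
}

#' Write a measures report to delimited text
#'
#' Writes an [measures_report()] table as CSV with the display value
#' rounded to 5 decimal places alongside a full-precision
#' machine-readable column (`value_full`), so round-tripping loses
#' nothing.
#'
#' @param report an `ineq_report`.
#' @param path output path.
#' @param sep field separator.
#' @return Invisibly, the data frame written.
#' @export
write_measures <- function(report, path, sep = ",") {
  if (!inherits(report, "ineq_report")) {
    ineq_stop("`report` must come from measures_report()", "ineq_argument_error")
  }
  out <- data.frame(
    measure = report$measure,
    name = report$name,
    polarity = report$polarity,
    scale_levels = report$scale_levels,
    lower = report$lower,
    upper = report$upper,
    value = round(report$value, 5),
    value_full = sprintf("%.17g", report$value),
    note = report$note,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = sep, row.names = FALSE, qmethod = "double")
  invisible(out)
}

#' Write the per-component distribution table
#'
#' @param d a [unit_distribution()].
#' @param path output path.
#' @param sep field separator.
#' @return Invisibly, the table written.
#' @export
write_distribution_table <- function(d, path, sep = ",") {
  tab <- distribution_table(d)
  utils::write.table(tab, path, sep = sep, row.names = FALSE)
  invisible(tab)
}
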