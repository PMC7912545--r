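#' Write an analysis report to disk
#'
#' JSON serialization keeps full double precision, so a written report reads
#' back numerically identical. CSV is available for matrix- or table-shaped
#' reports (e.g. a Nei distance matrix) and writes labelled rows/columns.
#'
#' @param report A report object (any of the summary lists produced by the
#'   package, a matrix, or a data frame).
#' @param path Output path.
#' @param format `"json"` or `"csv"`.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (is.null(report) || (is.list(report) && !length(report)) ||
      (!is.list(report) && !length(report)))
    stop("empty report")
  if (format == "json") {
    jsonlite::write_json(strip_classes(report), path, auto_unbox = TRUE,
                         digits = NA, na = "null", null = "null",
                         dataframe = "columns")
  } else {
    if (is.matrix(report)) {
      utils::write.csv(as.data.frame(report), path, row.names = TRUE)
    } else if (is.data.frame(report)) {
      utils::write.csv(report, path, row.names = FALSE)
    } else {
      stop("csv format supports matrix or data-frame reports; use json")
    }
  }
  invisible(path)
}

strip_classes <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  } else if (is.matrix(x)) {
    x <- as.data.frame(x)
  }
  x
}

#' Read back a JSON report
#'
#' @param path Path written by [write_report()] with `format = "json"`.
#' @return A nested list mirroring the report structure.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
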