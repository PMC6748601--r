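#' Write a summary report to CSV or JSON
#'
#' The CSV mirrors the published column order (name, type, heavy, light,
#' heavy CDRs, light CDRs, CDR-H3) with the threshold summary appended as
#' `#`-prefixed comment lines, so the data section stays machine-readable.
#' JSON serializes rows, raw fractions, thresholds and summary faithfully.
#' Both formats round-trip through [read_report()].
#'
#' @param report an `abmine_report`.
#' @param path output file.
#' @param format `"csv"` or `"json"`; default from the file extension.
#' @return the path, invisibly.
#' @export
write_report <- function(report, path,
                         format = c("auto", "csv", "json")) {
  stopifnot(inherits(report, "abmine_report"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "json") {
    payload <- list(rows = report$rows, raw = report$raw,
                    thresholds = report$thresholds,
                    threshold_counts = report$threshold_counts,
                    strata = report$strata)
    jsonlite::write_json(payload, path, digits = NA, na = "null",
                         auto_unbox = TRUE, dataframe = "columns")
  } else {
    con <- file(path, open = "w")
    on.exit(close(con))
    utils::write.csv(report$rows, con, row.names = FALSE, quote = FALSE)
    tc <- report$threshold_counts
    writeLines("# summary: column,op,threshold,count,percentage", con)
    writeLines(sprintf("# %s,%s,%d,%d,%.1f", tc$column, tc$op,
                       tc$threshold, tc$count, tc$percentage), con)
  }
  invisible(path)
}

#' Read a summary report written by [write_report()]
#'
#' @param path report file.
#' @param format `"csv"`, `"json"` or `"auto"` (from extension).
#' @return an `abmine_report`; threshold counts and strata are recomputed
#'   from the rows (CSV) or restored (JSON), which is equivalent because
#'   they are pure functions of the rows.
#' @export
read_report <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    ids <- as.data.frame(obj$rows, stringsAsFactors = FALSE)
    if (!is.null(obj$raw) && length(obj$raw))
      ids <- cbind(ids, as.data.frame(obj$raw))
    return(summary_report(ids, types = ids$type,
                          thresholds = as.integer(obj$thresholds)))
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  for (col in REPORT_COLUMNS) df[[col]] <- as.integer(df[[col]])
  summary_report(df, types = df$type)
}
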