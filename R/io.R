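#' Read a replicate frequency timecourse
#'
#' Reads a long-format delimited table of genotype-frequency
#' measurements and validates its schema.  Required columns: `time`
#' (or `day`), `replicate` (or `culture`), `frequency`; optional:
#' `mother`, `group`, `genotype`, `abundance`, `events`, `batch`.
#' Frequencies must lie in [0, 1]; violations are reported with their
#' row numbers.  The canonical dialect is tab-separated with a header;
#' comma-separated files are detected from the extension or can be
#' forced with `sep`.
#'
#' @param path Path to a TSV/CSV file.
#' @param sep Field separator; `NULL` picks "\\t" unless the file ends
#'   in `.csv`.
#' @return A validated data.frame sorted by replicate and time, with
#'   canonical column names `time` and `replicate`.
#' @export
read_timecourse <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = TRUE)
  nm <- names(d)
  if (!"time" %in% nm && "day" %in% nm) {
    d$time <- d$day
  }
  if (!"replicate" %in% nm && "culture" %in% nm) d$replicate <- d$culture
  missing_cols <- setdiff(c("time", "replicate", "frequency"), names(d))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (!is.numeric(d$time)) stop("column 'time' must be numeric")
  if (!is.numeric(d$frequency)) stop("column 'frequency' must be numeric")
  bad <- which(!is.finite(d$frequency) | d$frequency < 0 | d$frequency > 1)
  if (length(bad))
    stop("frequency outside [0, 1] at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  d[order(d$replicate, d$time), , drop = FALSE]
}

#' Write a timecourse table
#'
#' Writes the canonical tab-separated dialect read back by
#' [read_timecourse()].
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
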