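#' Read and write event-log TSV files
#'
#' Event logs are tab-separated, one row per trial, with missing values
#' written as `NA` and the `pstop` column rounded to 6 decimal places.
#'
#' @param events Event-log data.frame.
#' @param path File path.
#' @return `write_events_tsv` returns `path` invisibly; `read_events_tsv`
#'   returns the data.frame.
#' @export
write_events_tsv <- function(events, path) {
  if ("pstop" %in% names(events)) {
    events$pstop <- round(events$pstop, 6)
  }
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", na.strings = "NA",
                    stringsAsFactors = FALSE)
}

#' Read and write generic analysis tables (cohort, contrasts, reports)
#'
#' @param table A data.frame.
#' @param path File path.
#' @return `write_table_tsv` returns `path` invisibly; `read_table_tsv`
#'   returns the data.frame.
#' @export
write_table_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", na.strings = "NA",
                    stringsAsFactors = FALSE)
}
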