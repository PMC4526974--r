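#' Describe the physical layout of a query-log file
#'
#' A query log is a delimited text file with one record per submitted query.
#' The dialect maps the three logical columns (timestamp in integer seconds,
#' opaque user identifier, raw query text) onto physical column positions.
#' The default matches the common layout: tab-delimited,
#' `timestamp<TAB>user_id<TAB>query`, UTF-8.
#'
#' @param delimiter single delimiter character; must not be a square bracket
#'   (brackets delimit search-field tags inside query text).
#' @param columns named integer vector with entries `timestamp`, `user_id`,
#'   `query` giving 1-based column positions; the three must be distinct.
#' @param encoding file encoding name.
#' @return an object of class `log_dialect`.
#' @export
#' @examples
#' log_dialect()
#' log_dialect(delimiter = ",", columns = c(timestamp = 2, user_id = 1, query = 3))
log_dialect <- function(delimiter = "\t",
                        columns = c(timestamp = 1L, user_id = 2L, query = 3L),
                        encoding = "UTF-8") {
  if (!is.character(delimiter) || length(delimiter) != 1L || nchar(delimiter) != 1L) {
    pm_stop("`delimiter` must be a single character")
  }
  if (delimiter %in% c("[", "]")) {
    pm_stop("`delimiter` must not be a bracket character")
  }
  need <- c("timestamp", "user_id", "query")
  if (!all(need %in% names(columns))) {
    pm_stop("`columns` must name timestamp, user_id and query positions")
  }
  columns <- as.integer(columns[need])
  names(columns) <- need
  if (anyDuplicated(columns) || any(columns < 1L)) {
    pm_stop("`columns` must be three distinct positive positions")
  }
  structure(list(delimiter = delimiter, columns = columns, encoding = encoding),
            class = "log_dialect")
}

#' @export
print.log_dialect <- function(x, ...) {
  delim <- if (x$delimiter == "\t") "\\t" else x$delimiter
  cat("<log_dialect> delimiter='", delim, "' columns: ",
      paste(names(x$columns), x$columns, sep = "=", collapse = ", "),
      " encoding=", x$encoding, "\n", sep = "")
  invisible(x)
}

#' Read a query log
#'
#' Parses a delimited query-log file into one record per line, in file order.
#' No filtering happens here; records with empty user identifiers or empty
#' query text are retained and only removed by [clean_records()].
#'
#' @param path path to the log file.
#' @param dialect a [log_dialect()].
#' @param strict if `TRUE` (default) a line with too few columns or a
#'   non-numeric timestamp is an error naming the line; if `FALSE` such lines
#'   are skipped with a warning.
#' @return a `data.table` with columns `timestamp` (integer), `user_id`,
#'   `query_text` (character), one row per retained line, in file order.
#' @export
read_query_log <- function(path, dialect = log_dialect(), strict = TRUE) {
  if (!file.exists(path)) pm_stop("log file not found: ", path)
  lines <- readLines(path, encoding = dialect$encoding, warn = FALSE)
  if (length(lines) == 0L) {
    return(data.table(timestamp = integer(), user_id = character(),
                      query_text = character()))
  }
  # sentinel delimiter keeps trailing empty fields (strsplit drops them)
  parts <- strsplit(paste0(lines, dialect$delimiter), dialect$delimiter,
                    fixed = TRUE)
  ncols <- lengths(parts)
  need <- max(dialect$columns)
  short <- which(ncols < need)
  if (length(short)) {
    msg <- paste0("line ", short[1L], " has ", ncols[short[1L]],
                  " column(s); dialect needs ", need)
    if (strict) pm_stop(msg)
    warning(msg, "; ", length(short), " line(s) skipped", call. = FALSE)
    parts <- parts[-short]
  }
  get_col <- function(i) vapply(parts, `[[`, character(1L), i)
  ts_raw <- get_col(dialect$columns[["timestamp"]])
  ts <- suppressWarnings(as.integer(ts_raw))
  bad <- which(is.na(ts))
  if (length(bad)) {
    kept_line <- seq_along(lines)
    if (length(short)) kept_line <- kept_line[-short]
    msg <- paste0("line ", kept_line[bad[1L]], ": unparseable timestamp '",
                  ts_raw[bad[1L]], "'")
    if (strict) pm_stop(msg)
    warning(msg, "; ", length(bad), " line(s) skipped", call. = FALSE)
    parts <- parts[-bad]
    ts <- ts[-bad]
  }
  data.table(
    timestamp = ts,
    user_id = vapply(parts, `[[`, character(1L), dialect$columns[["user_id"]]),
    query_text = vapply(parts, `[[`, character(1L), dialect$columns[["query"]])
  )
}

#' Write records in query-log layout
#'
#' Inverse of [read_query_log()]: writes `timestamp`, `user_id`, `query_text`
#' into the physical columns the dialect describes. Reading the file back
#' with the same dialect reproduces the records.
#'
#' @param records a `data.table`/data.frame with `timestamp`, `user_id`,
#'   `query_text`.
#' @inheritParams read_query_log
#' @return `path`, invisibly.
#' @export
write_query_log <- function(records, path, dialect = log_dialect()) {
  records <- as.data.table(records)
  ncol_out <- max(dialect$columns)
  cols <- rep("", ncol_out)
  mat <- matrix("", nrow = nrow(records), ncol = ncol_out)
  mat[, dialect$columns[["timestamp"]]] <- as.character(records$timestamp)
  mat[, dialect$columns[["user_id"]]] <- records$user_id
  mat[, dialect$columns[["query"]]] <- records$query_text
  lines <- apply(mat, 1L, paste, collapse = dialect$delimiter)
  if (nrow(records) == 0L) lines <- character()
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Write a result table as TSV or JSON lines
#'
#' @param rows data.frame/data.table; rows share one schema.
#' @param path output path.
#' @param format `"tsv"` (tab-separated with header) or `"jsonl"`
#'   (one JSON object per line). Both round-trip through [read_table()].
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, format = c("tsv", "jsonl")) {
  format <- match.arg(format)
  rows <- as.data.table(rows)
  if (format == "tsv") {
    chr <- names(rows)[vapply(rows, is.character, logical(1L))]
    for (cl in chr) {
      if (any(grepl("[\t\n]", rows[[cl]]))) {
        pm_stop("column '", cl, "' contains tab/newline; TSV cannot represent it")
      }
    }
    fwrite(rows, path, sep = "\t", quote = FALSE, col.names = TRUE)
  } else {
    con <- file(path, open = "wb")
    on.exit(close(con))
    jsonlite::stream_out(as.data.frame(rows), con, verbose = FALSE)
  }
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @inheritParams write_table
#' @return a `data.table`.
#' @export
read_table <- function(path, format = c("tsv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) pm_stop("table not found: ", path)
  if (format == "tsv") {
    fread(path, sep = "\t", quote = "", header = TRUE, colClasses = NULL)
  } else {
    as.data.table(jsonlite::stream_in(file(path), verbose = FALSE))
  }
}
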