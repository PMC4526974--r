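#' Default user-identifier validity pattern
#'
#' A user identifier is considered well-formed when it is non-empty,
#' consists of printable non-whitespace ASCII, and is at most 64 characters
#' long. The pattern is deliberately permissive — only a handful of records
#' in a multi-million-line log are expected to fail it — and it is injectable
#' through [clean_records()] so stricter site-specific formats can be
#' configured.
#'
#' @return a single regular expression string.
#' @export
default_user_id_pattern <- function() "^[\\x21-\\x7e]{1,64}$"

#' Build a cleaning report from removal tallies
#'
#' The report mirrors the audit trail of log cleaning: how many records were
#' dropped for an empty user identifier, a malformed user identifier, or
#' empty query text, and what fraction of the input that represents.
#' `pct_removed` is `100 * n_removed / n_total` at full precision.
#'
#' @param n_total records in the input.
#' @param n_empty_user records with an empty user identifier.
#' @param n_malformed_user records whose user identifier fails the validity
#'   pattern.
#' @param n_empty_query records with empty or whitespace-only query text.
#' @return an object of class `cleaning_report`.
#' @export
#' @examples
#' r <- cleaning_report(2996301, 1146, 76, 77923)
#' round(r$pct_removed, 2)  # 2.64
cleaning_report <- function(n_total, n_empty_user, n_malformed_user, n_empty_query) {
  counts <- c(n_total, n_empty_user, n_malformed_user, n_empty_query)
  if (any(counts < 0)) pm_stop("cleaning counts must be non-negative")
  n_removed <- n_empty_user + n_malformed_user + n_empty_query
  if (n_removed > n_total) pm_stop("removed count exceeds total")
  structure(list(
    n_total = n_total,
    n_empty_user = n_empty_user,
    n_malformed_user = n_malformed_user,
    n_empty_query = n_empty_query,
    n_removed = n_removed,
    n_kept = n_total - n_removed,
    pct_removed = if (n_total > 0) 100 * n_removed / n_total else 0
  ), class = "cleaning_report")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("<cleaning_report>\n")
  cat(sprintf("  total records      %d\n", x$n_total))
  cat(sprintf("  empty user id      %d\n", x$n_empty_user))
  cat(sprintf("  malformed user id  %d\n", x$n_malformed_user))
  cat(sprintf("  empty query text   %d\n", x$n_empty_query))
  cat(sprintf("  removed            %d (%.2f%%)\n", x$n_removed, x$pct_removed))
  invisible(x)
}

#' Remove malformed query-log records
#'
#' Drops records with an empty user identifier, a user identifier failing the
#' validity predicate, or empty/whitespace-only query text (whitespace-only
#' text carries no search intent). A record failing several checks is counted
#' once, under the first failing reason in the order above. Surviving records
#' keep their input order; cleaning never reorders.
#'
#' @param records records as returned by [read_query_log()].
#' @param user_id_pattern a regular expression the user identifier must
#'   match, or a predicate function `f(user_id) -> logical`.
#' @return a list with `records` (the survivors, order preserved) and
#'   `report` (a [cleaning_report()]).
#' @export
clean_records <- function(records, user_id_pattern = default_user_id_pattern()) {
  records <- as.data.table(records)
  n_total <- nrow(records)
  if (n_total == 0L) {
    return(list(records = records, report = cleaning_report(0L, 0L, 0L, 0L)))
  }
  ok_id <- if (is.function(user_id_pattern)) {
    as.logical(user_id_pattern(records$user_id))
  } else {
    grepl(user_id_pattern, records$user_id, perl = TRUE)
  }
  empty_user <- records$user_id == ""
  malformed_user <- !empty_user & !ok_id
  empty_query <- !empty_user & !malformed_user & trimws(records$query_text) == ""
  keep <- !(empty_user | malformed_user | empty_query)
  report <- cleaning_report(n_total,
                            sum(empty_user),
                            sum(malformed_user),
                            sum(empty_query))
  list(records = records[keep], report = report)
}

#' Write a cleaning report as JSON
#'
#' @param report a [cleaning_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cleaning_report <- function(report, path) {
  stopifnot(inherits(report, "cleaning_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
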