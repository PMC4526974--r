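# sd that is 0 (not NA) for a single observation; distributions of one
# session/user still need a defined spread
sd0 <- function(x) if (length(x) < 2L) 0 else sd(x)

#' Queries-per-user summary and histogram
#'
#' Aggregates cleaned records into per-user query counts and summarises
#' them. The histogram reports, for each observed count, the percentage of
#' users submitting that many queries and the percentage of all queries they
#' account for.
#'
#' @param records cleaned records (`user_id` column required).
#' @return a list with `summary` (`n_users`, `n_queries`, `mean`, `sd`,
#'   `median`, `min`, `max`) and `histogram` (a `data.table` with
#'   `n_queries`, `n_users`, `pct_users`, `pct_queries`).
#' @export
queries_per_user <- function(records) {
  records <- as.data.table(records)
  if (nrow(records) == 0L) pm_stop("no records; cannot summarise queries per user")
  counts <- records[, .N, by = user_id]
  hist <- counts[, .(n_users = .N), by = .(n_queries = N)]
  setorder(hist, n_queries)
  hist[, pct_users := 100 * n_users / sum(n_users)]
  hist[, pct_queries := 100 * n_users * n_queries / nrow(records)]
  list(summary = list(n_users = nrow(counts),
                      n_queries = nrow(records),
                      mean = mean(counts$N),
                      sd = sd0(counts$N),
                      median = median(counts$N),
                      min = min(counts$N),
                      max = max(counts$N)),
       histogram = hist[])
}

#' Percentages of query types
#'
#' @param categories character vector of per-query categories
#'   (`informational`/`navigational`/`mixed`; `empty_translation` must have
#'   been removed upstream).
#' @return a `data.table` with `category`, `n`, `pct`; percentages sum to
#'   100 at full precision.
#' @export
query_type_proportions <- function(categories) {
  if (length(categories) == 0L) pm_stop("no categorized queries")
  lv <- c("informational", "navigational", "mixed")
  if (!all(categories %in% lv)) {
    pm_stop("unexpected category: ",
            paste(setdiff(unique(categories), lv), collapse = ", "))
  }
  n <- vapply(lv, function(l) sum(categories == l), integer(1L))
  data.table(category = lv, n = n, pct = 100 * n / sum(n))
}

#' Session-length distribution of one expertise group
#'
#' Tabulates sessions of the group by length and computes summary statistics
#' on the raw lengths (never on percentages). Extreme outliers are retained;
#' rows above `outlier_percentile` of the length distribution are only
#' flagged, not trimmed.
#'
#' @param sessions a sessions `data.table` carrying a `group` column (from
#'   [rollup_users()], or any table with `group` and `length`).
#' @param group `"experienced"` or `"nonexperienced"`.
#' @param outlier_percentile percentile above which a length is flagged.
#' @return an object of class `session_length_distribution`: a list with
#'   `group`, `counts` (a `data.table` of `length`, `n`, `pct`,
#'   `outlier`), `n_total`, and `summary` (`mean`, `sd`, `median`, `max`).
#' @export
length_distribution <- function(sessions, group, outlier_percentile = 0.999) {
  sessions <- as.data.table(sessions)
  if (!all(c("group", "length") %in% names(sessions))) {
    pm_stop("`sessions` needs columns group and length")
  }
  lens <- sessions$length[sessions$group == group]
  if (length(lens) == 0L) pm_stop("no sessions in group '", group, "'")
  counts <- data.table(length = lens)[, .(n = .N), by = length]
  setorder(counts, length)
  counts[, pct := 100 * n / sum(n)]
  cut <- stats::quantile(lens, probs = outlier_percentile, names = FALSE,
                         type = 1L)
  counts[, outlier := length > cut]
  structure(list(group = group,
                 counts = counts[],
                 n_total = length(lens),
                 summary = list(mean = mean(lens), sd = sd0(lens),
                                median = median(lens), max = max(lens))),
            class = "session_length_distribution")
}

#' @export
print.session_length_distribution <- function(x, ...) {
  cat("<session_length_distribution> group=", x$group, ", ", x$n_total,
      " sessions, lengths 1..", x$summary$max,
      sprintf(" (mean %.2f, sd %.2f, median %g)\n",
              x$summary$mean, x$summary$sd, x$summary$median), sep = "")
  invisible(x)
}

# N(L) for a distribution, 0 when the length was never observed
length_count <- function(distribution, L) {
  i <- match(L, distribution$counts$length)
  if (is.na(i)) 0L else distribution$counts$n[i]
}

#' Percentage of a group's sessions at one length
#'
#' `100 * N(L) / sum(N)`; a length never observed contributes 0%.
#'
#' @param distribution a [length_distribution()] result.
#' @param L session length, `>= 1`.
#' @return a percentage (full precision; round for reports).
#' @export
#' @examples
#' # from printed worked-example counts: 25,365 of 42,055 -> 60.31%
proportion_at_length <- function(distribution, L) {
  stopifnot(inherits(distribution, "session_length_distribution"), L >= 1)
  if (distribution$n_total == 0L) pm_stop("empty distribution")
  100 * length_count(distribution, L) / distribution$n_total
}

#' Decrease rate from the baseline session length
#'
#' `DR(L) = 1 - N(L) / N(baseline)`, reported as a percentage. The baseline
#' defaults to length 1 — the ideal retrieval where a single query satisfies
#' the information need — so the decrease rate measures how sharply session
#' counts fall off beyond it. The rate is 0 at the baseline, can reach 100
#' when no session has length `L`, and is returned negative (not clamped)
#' when `N(L) > N(baseline)`.
#'
#' @inheritParams proportion_at_length
#' @param baseline baseline length with `N(baseline) > 0`.
#' @return a percentage (full precision).
#' @export
decrease_rate <- function(distribution, L, baseline = 1L) {
  stopifnot(inherits(distribution, "session_length_distribution"),
            L >= 1, baseline >= 1)
  nb <- length_count(distribution, baseline)
  if (nb == 0L) pm_stop("no sessions at baseline length ", baseline)
  100 * (1 - length_count(distribution, L) / nb)
}

#' Decrease-rate table over a range of lengths
#'
#' @inheritParams decrease_rate
#' @param lengths lengths to tabulate (baseline is always included with
#'   rate 0).
#' @return an object of class `decrease_rate_table`: list with `group`,
#'   `baseline`, and `rates` (a `data.table` of `length`, `n`, `rate_pct`).
#' @export
decrease_rate_table <- function(distribution, lengths = 2:5, baseline = 1L) {
  lengths <- sort(unique(c(baseline, as.integer(lengths))))
  rates <- data.table(
    length = lengths,
    n = vapply(lengths, length_count, numeric(1L),
               distribution = distribution),
    rate_pct = vapply(lengths, decrease_rate, numeric(1L),
                      distribution = distribution, baseline = baseline))
  structure(list(group = distribution$group, baseline = baseline,
                 rates = rates),
            class = "decrease_rate_table")
}

#' @export
print.decrease_rate_table <- function(x, ...) {
  cat("<decrease_rate_table> group=", x$group, ", baseline length ",
      x$baseline, "\n", sep = "")
  tab <- copy(x$rates)
  tab[, rate_pct := round_pct(rate_pct)]
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Compare decrease rates between the two expertise groups
#'
#' Tabulates `DR_experienced(L) - DR_nonexperienced(L)` for the requested
#' lengths. Lengths absent from either table are reported with `NA`
#' difference, never imputed.
#'
#' @param table_experienced,table_nonexperienced [decrease_rate_table()]
#'   results sharing the same baseline.
#' @param lengths lengths to compare.
#' @return a `data.table` with `length`, `rate_experienced`,
#'   `rate_nonexperienced`, `difference`.
#' @export
compare_groups <- function(table_experienced, table_nonexperienced,
                           lengths = 2:5) {
  stopifnot(inherits(table_experienced, "decrease_rate_table"),
            inherits(table_nonexperienced, "decrease_rate_table"))
  if (table_experienced$baseline != table_nonexperienced$baseline) {
    pm_stop("decrease-rate tables must share a baseline")
  }
  le <- table_experienced$rates
  ln <- table_nonexperienced$rates
  out <- data.table(length = as.integer(lengths))
  out[, rate_experienced := le$rate_pct[match(length, le$length)]]
  out[, rate_nonexperienced := ln$rate_pct[match(length, ln$length)]]
  out[, difference := rate_experienced - rate_nonexperienced]
  out[]
}
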