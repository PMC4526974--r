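#' Run the full query-log analysis pipeline
#'
#' Composes the stages clean -> translate/categorize -> sessionize ->
#' classify -> stats into one reproducible run, logging input/output counts
#' at every stage boundary (removed records, empty translations,
#' per-category counts, session counts per group) and asserting conservation
#' (`records_in = records_kept + records_removed`) between stages. With an
#' `output_dir` all tables are written as TSV, the cleaning report and a run
#' manifest as JSON; reruns with an identical configuration produce
#' byte-identical files.
#'
#' @param records in-memory records (`timestamp`, `user_id`, `query_text`),
#'   e.g. from [generate_log()]; give either this or `log_path`.
#' @param log_path path to a query-log file read with `dialect`.
#' @param dialect a [log_dialect()].
#' @param lexicon a [build_lexicon()] result.
#' @param maps a [term_maps()] result.
#' @param window a [window_policy()].
#' @param rollup_policy `"relabel"` or `"keep"`, see [rollup_users()].
#' @param max_edit_distance fuzzy budget for tag resolution.
#' @param user_id_pattern validity pattern for [clean_records()].
#' @param output_dir optional directory for on-disk artifacts.
#' @param precision decimal places for percentages in written tables
#'   (in-memory results keep full precision).
#' @return an object of class `run_report` (a list; see the fields printed
#'   by its `print` method, all also accessible by name).
#' @export
run_pipeline <- function(records = NULL, log_path = NULL,
                         dialect = log_dialect(),
                         lexicon = default_lexicon(),
                         maps = default_term_maps(),
                         window = window_policy(),
                         rollup_policy = c("relabel", "keep"),
                         max_edit_distance = 2L,
                         user_id_pattern = default_user_id_pattern(),
                         output_dir = NULL,
                         precision = 2L) {
  rollup_policy <- match.arg(rollup_policy)
  if (is.null(records) == is.null(log_path)) {
    pm_stop("give exactly one of `records` or `log_path`")
  }
  if (!is.null(log_path)) records <- read_query_log(log_path, dialect)
  records <- as.data.table(records)

  report <- list(window = window, rollup_policy = rollup_policy,
                 max_edit_distance = max_edit_distance,
                 precision = precision)
  report$n_input <- nrow(records)

  # stage: cleaning
  cl <- clean_records(records, user_id_pattern)
  report$cleaning <- cl$report
  stopifnot(cl$report$n_kept + cl$report$n_removed == report$n_input)

  # stage: translation + categorization
  cat_res <- categorize_log(cl$records, lexicon, maps, max_edit_distance)
  report$n_empty_translation <- cat_res$n_empty_translation
  report$category_counts <- cat_res$category_counts
  stopifnot(sum(cat_res$category_counts) + cat_res$n_empty_translation ==
              cl$report$n_kept)

  # stage: session segmentation
  seg <- segment_sessions(cat_res$queries, window)
  stopifnot(nrow(seg$queries) == nrow(cat_res$queries))
  info <- informational_sessions(seg)
  report$n_sessions_total <- nrow(seg$sessions)
  report$n_sessions_informational <- nrow(info$sessions)
  report$n_sessions_excluded <- attr(info, "n_excluded")

  # stage: expertise classification
  labeled <- label_sessions(info, lexicon, max_edit_distance)
  rolled <- rollup_users(labeled, rollup_policy)
  report$n_sessions_experienced <- sum(rolled$sessions$group == "experienced")
  report$n_sessions_nonexperienced <-
    sum(rolled$sessions$group == "nonexperienced")
  report$n_users <- nrow(rolled$users)
  report$n_users_experienced <- sum(rolled$users$user_class == "experienced")
  report$dual_fraction <- rolled$dual_fraction
  report$rollup <- rolled
  stopifnot(report$n_sessions_experienced + report$n_sessions_nonexperienced ==
              report$n_sessions_informational)

  # stage: descriptive statistics (skipped for an empty log)
  if (nrow(cl$records) > 0L) {
    report$queries_per_user <- queries_per_user(cl$records)
    report$type_proportions <-
      query_type_proportions(cat_res$queries$category)
  }
  for (grp in c("experienced", "nonexperienced")) {
    if (any(rolled$sessions$group == grp)) {
      dist <- length_distribution(rolled$sessions, grp)
      report[[paste0("dist_", grp)]] <- dist
      report[[paste0("decrease_", grp)]] <- decrease_rate_table(dist)
    }
  }
  if (!is.null(report$decrease_experienced) &&
      !is.null(report$decrease_nonexperienced)) {
    report$decrease_comparison <- compare_groups(
      report$decrease_experienced, report$decrease_nonexperienced)
  }
  class(report) <- "run_report"
  if (!is.null(output_dir)) write_run_outputs(report, output_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  input records             %d\n", x$n_input))
  cat(sprintf("  removed by cleaning       %d (%.2f%%)\n",
              x$cleaning$n_removed, x$cleaning$pct_removed))
  cat(sprintf("  empty translations        %d\n", x$n_empty_translation))
  cc <- x$category_counts
  tot <- sum(cc)
  if (tot > 0) {
    cat(sprintf("  query types               informational %d (%.0f%%), navigational %d (%.0f%%), mixed %d (%.0f%%)\n",
                cc[["informational"]], 100 * cc[["informational"]] / tot,
                cc[["navigational"]], 100 * cc[["navigational"]] / tot,
                cc[["mixed"]], 100 * cc[["mixed"]] / tot))
  }
  cat(sprintf("  sessions                  %d total, %d informational retained\n",
              x$n_sessions_total, x$n_sessions_informational))
  cat(sprintf("  expertise (policy %s)  experienced %d, nonexperienced %d sessions\n",
              x$rollup_policy, x$n_sessions_experienced,
              x$n_sessions_nonexperienced))
  if (!is.null(x$dual_fraction) && !is.na(x$dual_fraction)) {
    cat(sprintf("  dual-behaviour users      %.2f%%\n", 100 * x$dual_fraction))
  }
  invisible(x)
}

# serialise all run artifacts; deterministic (no wall-clock content)
write_run_outputs <- function(report, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(output_dir, f)
  rp <- function(x) round_pct(x, report$precision)
  write_cleaning_report(report$cleaning, p("cleaning_report.json"))
  rolled <- report$rollup
  if (nrow(rolled$queries)) {
    write_table(rolled$queries[, .(user_id, timestamp, query_text, category,
                                   session_index, query_positive)],
                p("queries_labeled.tsv"))
  }
  sess <- copy(rolled$sessions)
  write_table(sess, p("sessions.tsv"))
  write_table(rolled$users, p("users.tsv"))
  if (!is.null(report$queries_per_user)) {
    hist <- copy(report$queries_per_user$histogram)
    hist[, `:=`(pct_users = rp(pct_users), pct_queries = rp(pct_queries))]
    write_table(hist, p("queries_per_user.tsv"))
  }
  if (!is.null(report$type_proportions)) {
    tp <- copy(report$type_proportions)
    tp[, pct := rp(pct)]
    write_table(tp, p("query_type_proportions.tsv"))
  }
  dists <- list()
  for (grp in c("experienced", "nonexperienced")) {
    d <- report[[paste0("dist_", grp)]]
    if (is.null(d)) next
    cnt <- copy(d$counts)
    cnt[, `:=`(group = grp, pct = rp(pct))]
    dists[[grp]] <- cnt
  }
  if (length(dists)) {
    write_table(rbindlist(dists), p("length_distributions.tsv"))
  }
  drs <- list()
  for (grp in c("experienced", "nonexperienced")) {
    d <- report[[paste0("decrease_", grp)]]
    if (is.null(d)) next
    r <- copy(d$rates)
    r[, `:=`(group = grp, rate_pct = rp(rate_pct))]
    drs[[grp]] <- r
  }
  if (length(drs)) write_table(rbindlist(drs), p("decrease_rates.tsv"))
  manifest <- list(
    package = "pmlog",
    version = as.character(utils::packageVersion("pmlog")),
    window_minutes = report$window$window_minutes,
    window_mode = report$window$mode,
    rollup_policy = report$rollup_policy,
    max_edit_distance = report$max_edit_distance,
    precision = report$precision,
    counts = list(
      n_input = report$n_input,
      n_removed = report$cleaning$n_removed,
      n_empty_translation = report$n_empty_translation,
      category_counts = as.list(report$category_counts),
      n_sessions_total = report$n_sessions_total,
      n_sessions_informational = report$n_sessions_informational,
      n_sessions_experienced = report$n_sessions_experienced,
      n_sessions_nonexperienced = report$n_sessions_nonexperienced,
      n_users = report$n_users,
      n_users_experienced = report$n_users_experienced))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(output_dir)
}
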