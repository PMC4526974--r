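#' Session segmentation window policy
#'
#' A session is a series of queries by one user within a small range of time
#' that serves one information need. The temporal constraint comes in two
#' flavours: `duration_cap` (default) bounds the total elapsed time of a
#' session, anchored at its first query — the reading that a "maximum window
#' length" most naturally supports, and the one matched by reported
#' task-completion times of 14-17 minutes; `gap_threshold` bounds the gap
#' between consecutive queries, the convention of much of the query-log
#' literature. The default window is 20 minutes.
#'
#' @param window_minutes positive window length in minutes.
#' @param mode `"duration_cap"` or `"gap_threshold"`.
#' @return an object of class `window_policy`.
#' @export
window_policy <- function(window_minutes = 20,
                          mode = c("duration_cap", "gap_threshold")) {
  mode <- match.arg(mode)
  if (!is.numeric(window_minutes) || length(window_minutes) != 1L ||
      window_minutes <= 0) {
    pm_stop("`window_minutes` must be a positive number")
  }
  structure(list(window_minutes = window_minutes,
                 window_seconds = window_minutes * 60,
                 mode = mode),
            class = "window_policy")
}

#' @export
print.window_policy <- function(x, ...) {
  cat("<window_policy> ", x$window_minutes, " min, mode=", x$mode, "\n",
      sep = "")
  invisible(x)
}

# session ids for one user's time-sorted queries (streaming, O(n))
assign_session_ids <- function(ts, type, window_s, mode) {
  n <- length(ts)
  sid <- integer(n)
  sid[1L] <- 1L
  cur <- 1L
  anchor <- ts[1L]
  if (n > 1L) {
    for (i in 2:n) {
      shift <- type[i] != type[i - 1L] ||
        (mode == "duration_cap" && ts[i] - anchor > window_s) ||
        (mode == "gap_threshold" && ts[i] - ts[i - 1L] > window_s)
      if (shift) {
        cur <- cur + 1L
        anchor <- ts[i]
      }
      sid[i] <- cur
    }
  }
  sid
}

#' Segment categorized queries into sessions
#'
#' Groups records by user, sorts each user's records by timestamp (stable on
#' ties, preserving input order), and opens a new session whenever (a) the
#' temporal constraint of the [window_policy()] is violated, or (b) the
#' query's effective intent differs from the previous query's — the
#' session-shift rule. Mixed queries act as navigational for boundary
#' purposes. Every input query belongs to exactly one session, and a session
#' is homogeneous in effective type by construction.
#'
#' @param queries a `data.table` with `timestamp`, `user_id`, `category`
#'   (from [categorize_log()]; `empty_translation` rows must already be
#'   removed). Extra columns are carried along.
#' @param policy a [window_policy()].
#' @return an object of class `session_set`: a list with `queries` (input
#'   rows plus `session_id` — globally unique integer — and `session_index`
#'   within the user) and `sessions` (one row per session: `user_id`,
#'   `session_index`, `session_id`, `start`, `end`, `length`,
#'   `session_type` of `"informational"` or `"navigational"`).
#' @export
segment_sessions <- function(queries, policy = window_policy()) {
  queries <- as.data.table(queries)
  stopifnot(inherits(policy, "window_policy"))
  need <- c("timestamp", "user_id", "category")
  if (!all(need %in% names(queries))) {
    pm_stop("`queries` needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(queries) && any(queries$timestamp < 0)) {
    pm_stop("negative timestamps are not allowed")
  }
  if (nrow(queries) && any(queries$category == "empty_translation")) {
    pm_stop("empty_translation queries must be removed before segmentation")
  }
  q <- copy(queries)
  if (nrow(q) == 0L) {
    q[, `:=`(session_id = integer(), session_index = integer(),
             eff_type = character())]
    sessions <- data.table(user_id = character(), session_index = integer(),
                           session_id = integer(), start = integer(),
                           end = integer(), length = integer(),
                           session_type = character())
    return(structure(list(queries = q, sessions = sessions, policy = policy),
                     class = "session_set"))
  }
  q[, eff_type := ifelse(category == "informational", "informational",
                         "navigational")]
  q[, .row := .I]
  setorder(q, user_id, timestamp, .row)  # stable within user
  q[, session_index := assign_session_ids(timestamp, eff_type,
                                          policy$window_seconds, policy$mode),
    by = user_id]
  q[, session_id := .GRP, by = .(user_id, session_index)]
  sessions <- q[, .(user_id = user_id[1L],
                    session_index = session_index[1L],
                    start = timestamp[1L],
                    end = timestamp[.N],
                    length = .N,
                    session_type = eff_type[1L]),
                by = session_id]
  setcolorder(sessions, c("user_id", "session_index", "session_id",
                          "start", "end", "length", "session_type"))
  q[, .row := NULL]
  structure(list(queries = q, sessions = sessions, policy = policy),
            class = "session_set")
}

#' @export
print.session_set <- function(x, ...) {
  cat("<session_set> ", nrow(x$sessions), " sessions over ",
      nrow(x$queries), " queries (",
      sum(x$sessions$session_type == "informational"), " informational, ",
      sum(x$sessions$session_type == "navigational"),
      " navigational/mixed)\n", sep = "")
  invisible(x)
}

#' Keep only informational sessions
#'
#' Navigational search tags serve document lookup rather than information
#' needs, so navigational (and mixed, which act as navigational) sessions
#' are excluded from the behavioural analysis. Order among survivors is
#' preserved; the number of excluded sessions is attached as attribute
#' `n_excluded`.
#'
#' @param session_set a [segment_sessions()] result.
#' @return a `session_set` containing informational sessions only.
#' @export
informational_sessions <- function(session_set) {
  stopifnot(inherits(session_set, "session_set"))
  keep_ids <- session_set$sessions[session_type == "informational", session_id]
  out <- structure(list(
    queries = session_set$queries[session_id %in% keep_ids],
    sessions = session_set$sessions[session_type == "informational"],
    policy = session_set$policy
  ), class = "session_set")
  attr(out, "n_excluded") <- nrow(session_set$sessions) - nrow(out$sessions)
  out
}
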