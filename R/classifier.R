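#' Detect system-function usage in raw query text
#'
#' Computes the four expertise indicators for each query string, always from
#' the original (pre-translation) text — translation-added tags never count:
#' \describe{
#'   \item{has_field_tag}{a user-written bracketed tag that resolves in the
#'     lexicon (exact, alias or fuzzy);}
#'   \item{has_mesh_tag}{a resolving tag from the MeSH family;}
#'   \item{has_truncation}{a terminal asterisk on a word (mid-word asterisks
#'     are ignored — the wildcard is only honoured word-finally);}
#'   \item{has_history_ref}{a search-history token of the form `#N`.}
#' }
#' A query is system-function-positive when any flag is true. Boolean
#' operators alone do not mark expertise.
#'
#' @param query_text character vector of raw query strings.
#' @param lexicon a [build_lexicon()] result.
#' @param max_edit_distance fuzzy budget for tag resolution.
#' @return a `data.table`, one row per input query, with the four logical
#'   flag columns and `positive`.
#' @export
#' @examples
#' query_uses_system_functions(c("hypertension [MeSH]", "high blood pressure",
#'                               "nutrition*"))
query_uses_system_functions <- function(query_text,
                                        lexicon = default_lexicon(),
                                        max_edit_distance = 2L) {
  uq <- unique(query_text)
  tagflags <- vapply(uq, function(txt) {
    occ <- extract_tags(txt, lexicon, max_edit_distance)
    c(field = any(!is.na(occ$canonical)),
      mesh = any(occ$mesh, na.rm = TRUE))
  }, logical(2L))
  i <- match(query_text, uq)
  out <- data.table(
    has_field_tag = tagflags["field", i],
    has_mesh_tag = tagflags["mesh", i],
    has_truncation = grepl("[[:alnum:]]\\*([^[:alnum:]*]|$)", query_text),
    has_history_ref = grepl("(^|[^[:alnum:]#])#[0-9]+([^[:alnum:]]|$)",
                            query_text)
  )
  out[, positive := has_field_tag | has_mesh_tag | has_truncation |
        has_history_ref]
  out[]
}

#' Label informational sessions as experienced or nonexperienced
#'
#' A session is experienced when at least one of its queries uses a system
#' function (field tag, MeSH tag, truncation, or history reference in the
#' original query text); otherwise nonexperienced. The input must contain
#' informational sessions only (apply [informational_sessions()] first).
#'
#' @param session_set an informational-only `session_set`.
#' @inheritParams query_uses_system_functions
#' @return the `session_set` with an `expertise_label` column on `sessions`
#'   and a `query_positive` flag on `queries`.
#' @export
label_sessions <- function(session_set, lexicon = default_lexicon(),
                           max_edit_distance = 2L) {
  stopifnot(inherits(session_set, "session_set"))
  if (nrow(session_set$sessions) &&
      any(session_set$sessions$session_type != "informational")) {
    pm_stop("label_sessions expects informational sessions only; ",
            "apply informational_sessions() first")
  }
  out <- session_set
  q <- copy(out$queries)
  s <- copy(out$sessions)
  if (nrow(q)) {
    flags <- query_uses_system_functions(q$query_text, lexicon,
                                         max_edit_distance)
    q[, query_positive := flags$positive]
    lab <- q[, .(expertise_label = if (any(query_positive)) "experienced"
                 else "nonexperienced"), by = session_id]
    s[lab, expertise_label := i.expertise_label, on = "session_id"]
  } else {
    q[, query_positive := logical()]
    s[, expertise_label := character()]
  }
  out$queries <- q
  out$sessions <- s
  out
}

#' Roll users up from their session labels
#'
#' A user with at least one experienced session is an experienced user, even
#' when they also performed nonexperienced sessions (dual-behaviour users:
#' knowing the system functions is what defines experience). Under
#' `policy = "relabel"` (default) every session of an experienced user is
#' counted in the experienced group; under `policy = "keep"` sessions retain
#' their computed labels and only the user class moves. The fraction of
#' dual-behaviour users is reported.
#'
#' @param session_set a [label_sessions()] result.
#' @param policy `"relabel"` or `"keep"`.
#' @return an object of class `user_rollup`: a list with `users` (one row per
#'   user: session tallies and `user_class`), `sessions` (labelled sessions
#'   plus a `group` column holding the counted group), `queries`,
#'   `dual_fraction` (share of users with both session labels), and `policy`.
#' @export
rollup_users <- function(session_set, policy = c("relabel", "keep")) {
  policy <- match.arg(policy)
  stopifnot(inherits(session_set, "session_set"))
  s <- copy(session_set$sessions)
  if (!"expertise_label" %in% names(s)) {
    pm_stop("sessions are unlabeled; run label_sessions() first")
  }
  if (nrow(s) == 0L) {
    users <- data.table(user_id = character(),
                        n_sessions_experienced = integer(),
                        n_sessions_nonexperienced = integer(),
                        user_class = character())
    s[, group := character()]
    return(structure(list(users = users, sessions = s,
                          queries = session_set$queries,
                          dual_fraction = NA_real_, policy = policy),
                     class = "user_rollup"))
  }
  users <- s[, .(n_sessions_experienced = sum(expertise_label == "experienced"),
                 n_sessions_nonexperienced =
                   sum(expertise_label == "nonexperienced")),
             by = user_id]
  users[, user_class := ifelse(n_sessions_experienced >= 1L,
                               "experienced", "nonexperienced")]
  dual <- users[, mean(n_sessions_experienced > 0L &
                         n_sessions_nonexperienced > 0L)]
  s[users, user_class := i.user_class, on = "user_id"]
  if (policy == "relabel") {
    s[, group := ifelse(user_class == "experienced", "experienced",
                        expertise_label)]
  } else {
    s[, group := expertise_label]
  }
  s[, user_class := NULL]
  structure(list(users = users, sessions = s, queries = session_set$queries,
                 dual_fraction = dual, policy = policy),
            class = "user_rollup")
}

#' @export
print.user_rollup <- function(x, ...) {
  cat("<user_rollup> ", nrow(x$users), " users (",
      sum(x$users$user_class == "experienced"), " experienced); ",
      nrow(x$sessions), " sessions (",
      sum(x$sessions$group == "experienced"), " counted experienced, policy=",
      x$policy, "); dual-behaviour fraction ",
      if (is.na(x$dual_fraction)) "NA" else
        sprintf("%.2f%%", 100 * x$dual_fraction), "\n", sep = "")
  invisible(x)
}
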