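# run code under a fixed seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, fun) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  fun()
}

# generator vocabularies (memoised)
synth_vocab <- function() {
  if (is.null(.pmlog_env$vocab)) {
    rd <- function(f) readLines(system.file("extdata", f, package = "pmlog",
                                            mustWork = TRUE))
    .pmlog_env$vocab <- list(mesh = rd("mesh_terms.txt"),
                             lay = rd("lay_terms.txt"),
                             journals = rd("journals.txt"),
                             authors = rd("author_names.txt"))
  }
  .pmlog_env$vocab
}

#' Configuration of the synthetic query-log generator
#'
#' The generator emulates the statistical structure a full-day log analysis
#' assumes: per-user bursts of temporally clustered queries (sessions), a
#' mixture of experienced users (who write field tags, MeSH tags, truncation
#' wildcards and history references) and nonexperienced users (plain
#' natural-language queries), interleaved navigational and mixed queries,
#' and occasional malformed records. Defaults are calibrated once to the
#' magnitudes a full-day PubMed log exhibits; see the methods vignette.
#'
#' Sessions per user follow Poisson(`lambda`) + 1. Informational session
#' lengths are geometric with group-specific success probability
#' (`p_experienced`, `p_nonexperienced`), so the group's share of length-1
#' sessions equals `p`; navigational/mixed bursts use `p_short`. Within a
#' session, gaps are truncated-exponential seconds (and are compressed when
#' a long session would otherwise exceed 95% of the window, so a session
#' never straddles the segmentation window); between sessions the gap is
#' `window + offset_s + Exp(mean_s)`, strictly above the window. Session
#' types are drawn per session with probabilities reweighted by expected
#' session length so that `p_navigational_query`/`p_mixed_query` are hit at
#' the *query* level in expectation.
#'
#' @param n_users number of users.
#' @param fraction_experienced probability a user is experienced.
#' @param sessions_per_user list with `lambda`.
#' @param session_length list with `p_experienced`, `p_nonexperienced`,
#'   `p_short`.
#' @param intra_session_gap list with `mean_s`, `min_s`, `max_s` (seconds).
#' @param inter_session_gap list with `offset_s` (> 0, keeps the support
#'   above the window) and `mean_s`.
#' @param window_minutes segmentation window the gap structure must respect.
#' @param p_tag_use,p_truncation,p_history_ref per-query probabilities of
#'   each system function in experienced users' informational queries.
#' @param p_navigational_query,p_mixed_query query-level type probabilities.
#' @param tag_typo_rate probability that a bracketed tag surface receives
#'   one random character edit (see [corrupt_tags()]).
#' @param p_malformed_record target share of malformed records (empty user
#'   id, unusual user id, or empty query text) among all emitted records.
#' @param day_seconds length of the simulated day; timestamps stay below it.
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_users = 1000L,
                         fraction_experienced = 0.06,
                         sessions_per_user = list(lambda = 0.8),
                         session_length = list(p_experienced = 0.60,
                                               p_nonexperienced = 0.47,
                                               p_short = 0.8),
                         intra_session_gap = list(mean_s = 45, min_s = 2,
                                                  max_s = 120),
                         inter_session_gap = list(offset_s = 300,
                                                  mean_s = 1800),
                         window_minutes = 20,
                         p_tag_use = 0.7,
                         p_truncation = 0.10,
                         p_history_ref = 0.05,
                         p_navigational_query = 0.26,
                         p_mixed_query = 0.05,
                         tag_typo_rate = 0,
                         p_malformed_record = 0.0271,
                         day_seconds = 86400L,
                         seed = 1L) {
  cfg <- structure(as.list(environment()), class = "synth_config")
  probs <- c(fraction_experienced, p_tag_use, p_truncation, p_history_ref,
             p_navigational_query, p_mixed_query, tag_typo_rate,
             p_malformed_record,
             session_length$p_experienced, session_length$p_nonexperienced,
             session_length$p_short)
  if (any(probs < 0 | probs > 1)) pm_stop("probabilities must lie in [0, 1]")
  if (p_navigational_query + p_mixed_query > 1) {
    pm_stop("p_navigational_query + p_mixed_query must be <= 1")
  }
  if (n_users < 1L) pm_stop("n_users must be >= 1")
  if (sessions_per_user$lambda < 0) pm_stop("sessions_per_user$lambda must be >= 0")
  if (any(unlist(session_length) <= 0)) pm_stop("geometric p must be > 0")
  if (inter_session_gap$offset_s <= 0) {
    pm_stop("inter_session_gap$offset_s must be > 0: the inter-session gap ",
            "support must lie strictly above the window")
  }
  with(intra_session_gap, {
    if (min_s < 0 || max_s <= min_s || mean_s <= 0) {
      pm_stop("invalid intra_session_gap")
    }
  })
  if (window_minutes <= 0) pm_stop("window_minutes must be > 0")
  cfg
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config> ", x$n_users, " users, ",
      100 * x$fraction_experienced, "% experienced, seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}

# one query text; returns list(text, uses_fn) -- uses_fn only meaningful for
# informational queries
synth_query_text <- function(type, experienced, cfg, vocab) {
  # informational tag surfaces with a usage-weighted mix of short codes and
  # spelled-out alias forms, echoing the alias variety real logs show
  info_tags <- c("mesh", "mh", "majr", "ti", "tiab", "tw",
                 "title", "mesh terms", "text words", "major")
  info_tag_w <- c(0.20, 0.15, 0.08, 0.12, 0.05, 0.05,
                  0.15, 0.10, 0.05, 0.05)
  if (type == "informational") {
    if (experienced) {
      tagged <- runif(1) < cfg$p_tag_use
      trunc <- runif(1) < cfg$p_truncation
      hist <- runif(1) < cfg$p_history_ref
      base <- if (tagged) {
        paste0(sample(vocab$mesh, 1L), " [",
               sample(info_tags, 1L, prob = info_tag_w), "]")
      } else {
        sample(vocab$lay, 1L)
      }
      if (trunc) {
        stem <- substr(strsplit(sample(vocab$mesh, 1L), " ")[[1L]][1L], 1L, 5L)
        base <- paste0(base, " AND ", stem, "*")
      }
      if (hist) base <- paste0("#", sample(1:3, 1L), " AND ", base)
      list(text = base, uses_fn = tagged || trunc || hist)
    } else {
      u <- runif(1)
      text <- if (u < 0.15) {
        paste0('"', sample(vocab$lay, 1L), '"')
      } else if (u < 0.35) {
        paste(sample(vocab$lay, 2L), collapse = " AND ")
      } else {
        sample(vocab$lay, 1L)
      }
      list(text = text, uses_fn = FALSE)
    }
  } else if (type == "navigational") {
    u <- runif(1)
    text <- if (u < 0.4) {
      paste0(sample(vocab$authors, 1L), " [au]")
    } else if (u < 0.6) {
      paste0(sample(vocab$authors, 1L), " [au] AND ",
             sample(vocab$authors, 1L), " [author]")
    } else if (u < 0.85) {
      paste0(sample(vocab$journals, 1L), " [ta]")
    } else {
      paste0(as.integer(floor(runif(1, 1e7, 3e7))), " [pmid]")
    }
    list(text = text, uses_fn = NA)
  } else {  # mixed: user informational tag + a term the journal map will tag
    list(text = paste0(sample(vocab$mesh, 1L), " [",
                       sample(c("ti", "mh", "tiab"), 1L), "] AND ",
                       sample(vocab$journals, 1L)),
         uses_fn = NA)
  }
}

# integer intra-session gaps whose running sum stays within 95% of the window
synth_intra_gaps <- function(k, cfg) {
  if (k == 0L) return(integer())
  g <- rexp(k, rate = 1 / cfg$intra_session_gap$mean_s)
  g <- pmin(pmax(g, cfg$intra_session_gap$min_s), cfg$intra_session_gap$max_s)
  g <- pmax(1L, as.integer(round(g)))
  cap <- floor(0.95 * cfg$window_minutes * 60)
  if (sum(g) > cap) g <- pmax(1L, as.integer(floor(g * cap / sum(g))))
  g
}

#' Generate a synthetic query log with ground truth
#'
#' Emits a full-day query log with the structure described in
#' [synth_config()], together with record-level, session-level and
#' user-level ground truth, so that every pipeline stage can be validated
#' against known labels. The emitted records are sorted by timestamp (stable
#' across users); ground-truth rows align one-to-one with records through
#' `record_id`.
#'
#' @param config a [synth_config()].
#' @return an object of class `synthetic_log`: a list with
#'   \describe{
#'     \item{records}{`data.table` of `timestamp`, `user_id`, `query_text` —
#'       the same layout [read_query_log()] produces;}
#'     \item{truth}{list with `records` (per-record `record_id`,
#'       `true_category`, `true_session_index`, `user_class`,
#'       `uses_system_function`, `malformed`), `sessions` (per true session:
#'       type, length, start/end, `experienced` label for informational
#'       sessions), `users` (class and dual-behaviour flag), `edits` (tag
#'       corruption log), and the echoed `config`.}
#'   }
#' @export
generate_log <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  vocab <- synth_vocab()
  with_seed(config$seed, function() {
    window_s <- config$window_minutes * 60
    rec <- vector("list", config$n_users * 2L)
    nrec <- 0L
    sess_rows <- vector("list", config$n_users * 2L)
    nsess <- 0L
    user_rows <- vector("list", config$n_users)
    p_nav <- config$p_navigational_query
    p_mix <- config$p_mixed_query
    p_info <- 1 - p_nav - p_mix
    for (u in seq_len(config$n_users)) {
      uid <- sprintf("u%06d", u)
      experienced <- runif(1) < config$fraction_experienced
      p_len <- if (experienced) config$session_length$p_experienced
               else config$session_length$p_nonexperienced
      # session-type draw reweighted by expected length so the configured
      # type mix holds at the query level in expectation
      w <- c(informational = p_info * p_len,
             navigational = p_nav * config$session_length$p_short,
             mixed = p_mix * config$session_length$p_short)
      n_sess <- rpois(1L, config$sessions_per_user$lambda) + 1L
      types <- if (sum(w) == 0) rep("informational", n_sess) else
        sample(names(w), n_sess, replace = TRUE, prob = w / sum(w))
      t_now <- as.integer(floor(runif(1, 0, config$day_seconds * 0.5)))
      emitted <- 0L
      info_labels <- logical(0L)
      for (s in seq_len(n_sess)) {
        type <- types[s]
        len <- if (type == "informational") rgeom(1L, p_len) + 1L
               else rgeom(1L, config$session_length$p_short) + 1L
        gaps <- synth_intra_gaps(len - 1L, config)
        ts <- t_now + c(0L, cumsum(gaps))
        if (ts[len] >= config$day_seconds) break  # day over for this user
        qs <- lapply(seq_len(len), function(i) {
          synth_query_text(type, experienced, config, vocab)
        })
        texts <- vapply(qs, `[[`, character(1L), "text")
        flags <- vapply(qs, `[[`, logical(1L), "uses_fn")
        emitted <- emitted + 1L
        nrec <- nrec + 1L
        rec[[nrec]] <- data.table(
          timestamp = ts, user_id = uid, query_text = texts,
          true_category = type, true_session_index = emitted,
          user_class = if (experienced) "experienced" else "nonexperienced",
          uses_system_function = flags)
        nsess <- nsess + 1L
        sess_rows[[nsess]] <- data.table(
          user_id = uid, session_index = emitted, session_type = type,
          length = len, start = ts[1L], end = ts[len],
          experienced = if (type == "informational") any(flags) else NA)
        if (type == "informational") info_labels <- c(info_labels, any(flags))
        t_now <- ts[len] + window_s + config$inter_session_gap$offset_s +
          as.integer(round(rexp(1L, 1 / config$inter_session_gap$mean_s)))
      }
      user_rows[[u]] <- data.table(
        user_id = uid,
        user_class = if (experienced) "experienced" else "nonexperienced",
        n_sessions = emitted,
        n_informational_sessions = length(info_labels),
        dual = length(info_labels) > 0L && any(info_labels) && !all(info_labels))
    }
    good <- rbindlist(rec[seq_len(nrec)])
    truth_sessions <- rbindlist(sess_rows[seq_len(nsess)])
    truth_users <- rbindlist(user_rows)
    good[, malformed := FALSE]
    # malformed records: extra lines the cleaning stage must remove
    p_bad <- config$p_malformed_record
    n_bad <- if (p_bad > 0) rbinom(1L, nrow(good), p_bad / (1 - p_bad)) else 0L
    if (n_bad > 0L) {
      kind <- sample(c("empty_query", "empty_user", "unusual_user"), n_bad,
                     replace = TRUE, prob = c(0.98456, 0.01448, 0.00096))
      bad <- data.table(
        timestamp = as.integer(floor(runif(n_bad, 0, config$day_seconds))),
        user_id = ifelse(kind == "empty_query",
                         sample(truth_users$user_id, n_bad, replace = TRUE),
                         ifelse(kind == "empty_user", "", "anon user")),
        query_text = ifelse(kind == "empty_query", "",
                            sample(vocab$lay, n_bad, replace = TRUE)),
        true_category = NA_character_,
        true_session_index = NA_integer_,
        user_class = NA_character_,
        uses_system_function = NA,
        malformed = TRUE)
      good <- rbind(good, bad)
    }
    setorder(good, timestamp)  # stable: generation order breaks ties
    good[, record_id := .I]
    edits <- data.table(record_id = integer(), original = character(),
                        corrupted = character())
    if (config$tag_typo_rate > 0) {
      cr <- corrupt_tags(good[, .(timestamp, user_id, query_text)],
                         config$tag_typo_rate,
                         seed = config$seed + 1L)
      good[, query_text := cr$records$query_text]
      edits <- cr$edits
    }
    structure(list(
      records = good[, .(timestamp, user_id, query_text)],
      truth = list(
        records = good[, .(record_id, timestamp, user_id, true_category,
                           true_session_index, user_class,
                           uses_system_function, malformed)],
        sessions = truth_sessions,
        users = truth_users,
        edits = edits,
        config = config)
    ), class = "synthetic_log")
  })
}

#' @export
print.synthetic_log <- function(x, ...) {
  cat("<synthetic_log> ", nrow(x$records), " records, ",
      nrow(x$truth$users), " users, ", nrow(x$truth$sessions),
      " true sessions (seed ", x$truth$config$seed, ")\n", sep = "")
  invisible(x)
}

# one random character edit on a tag surface; length-1 surfaces only get
# substitutions/insertions
random_edit <- function(s) {
  n <- nchar(s)
  ops <- c("substitute", "insert", if (n >= 2L) c("delete", "transpose"))
  op <- sample(ops, 1L)
  letters_pool <- letters
  i <- sample(seq_len(n), 1L)
  switch(op,
    substitute = {
      repl <- sample(setdiff(letters_pool, tolower(substr(s, i, i))), 1L)
      paste0(substr(s, 1L, i - 1L), repl, substr(s, i + 1L, n))
    },
    insert = {
      j <- sample(0:n, 1L)
      paste0(substr(s, 1L, j), sample(letters_pool, 1L),
             substr(s, j + 1L, n))
    },
    delete = paste0(substr(s, 1L, i - 1L), substr(s, i + 1L, n)),
    transpose = {
      j <- if (i == n) i - 1L else i
      paste0(substr(s, 1L, j - 1L), substr(s, j + 1L, j + 1L),
             substr(s, j, j), substr(s, j + 2L, n))
    })
}

#' Inject typos into bracketed tag surfaces
#'
#' Emulates misspelled search tags (e.g. `[Atuhor]`): a seeded fraction of
#' bracketed tag surfaces receive one random character edit (substitution,
#' insertion, deletion or adjacent transposition). Every edit is recorded so
#' recovery by fuzzy tag resolution can be scored against ground truth.
#'
#' @param records a records table with `query_text`.
#' @param tag_typo_rate per-occurrence corruption probability.
#' @param seed integer seed.
#' @return a list with `records` (corrupted copy) and `edits`
#'   (`record_id` = row number, `original`, `corrupted` tag surfaces).
#' @export
corrupt_tags <- function(records, tag_typo_rate, seed = 1L) {
  stopifnot(tag_typo_rate >= 0, tag_typo_rate <= 1)
  records <- copy(as.data.table(records))
  edits <- data.table(record_id = integer(), original = character(),
                      corrupted = character())
  if (tag_typo_rate == 0 || nrow(records) == 0L) {
    return(list(records = records, edits = edits))
  }
  with_seed(seed, function() {
    erows <- list()
    txts <- records$query_text
    for (r in seq_along(txts)) {
      ml <- gregexpr("\\[[^][]*\\]", txts[r])
      if (ml[[1L]][1L] == -1L) next
      pieces <- regmatches(txts[r], ml)[[1L]]
      changed <- FALSE
      for (k in seq_along(pieces)) {
        inner <- substr(pieces[k], 2L, nchar(pieces[k]) - 1L)
        # typos are modelled on word-like surfaces: a single edit in a
        # two-letter code yields a different code, not a recognisable
        # misspelling, so short abbreviations are left intact
        if (nchar(inner) < 4L) next
        if (runif(1) >= tag_typo_rate) next
        new_inner <- random_edit(inner)
        erows[[length(erows) + 1L]] <- data.table(
          record_id = r, original = inner, corrupted = new_inner)
        pieces[k] <- paste0("[", new_inner, "]")
        changed <- TRUE
      }
      if (changed) {
        regmatches(txts[r], ml) <- list(pieces)
      }
    }
    records[, query_text := txts]
    list(records = records,
         edits = if (length(erows)) rbindlist(erows) else edits)
  })
}
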