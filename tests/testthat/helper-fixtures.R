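library(data.table)

# small record builder
make_records <- function(ts, user, query) {
  data.table(timestamp = as.integer(ts), user_id = user, query_text = query)
}

# independent quadratic session oracle: repeatedly take the longest prefix
# that is a valid single session, re-checking validity from scratch
brute_session_ids <- function(ts, type, window_s, mode) {
  valid <- function(i, k) {
    if (any(type[i:k] != type[i])) return(FALSE)
    if (mode == "duration_cap") {
      ts[k] - ts[i] <= window_s
    } else {
      k == i || all(diff(ts[i:k]) <= window_s)
    }
  }
  n <- length(ts)
  sid <- integer(n)
  cur <- 0L
  i <- 1L
  while (i <= n) {
    k <- i
    while (k < n && valid(i, k + 1L)) k <- k + 1L
    cur <- cur + 1L
    sid[i:k] <- cur
    i <- k + 1L
  }
  sid
}

# random categorized mini-log for property tests
random_mini_log <- function(n_users = 3L, max_q = 50L, max_t = 7200L) {
  rows <- lapply(seq_len(n_users), function(u) {
    m <- sample.int(max_q, 1L)
    data.table(
      timestamp = sort(sample.int(max_t, m, replace = TRUE)),
      user_id = paste0("u", u),
      query_text = "q",
      category = sample(c("informational", "navigational", "mixed"), m,
                        replace = TRUE, prob = c(0.7, 0.2, 0.1)))
  })
  rbindlist(rows)
}

# tiny lexicon used where the full default is overkill
tiny_lexicon <- function() {
  build_lexicon(data.frame(
    canonical = c("Author", "Journal", "Title", "MeSH Terms", "All Fields"),
    intent = c("navigational", "navigational", "informational",
               "informational", "informational"),
    mesh = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    aliases = c("au,auth,author name", "ta,jour", "ti", "mh,mesh", "all")))
}
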