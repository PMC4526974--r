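cat_rec <- function(ts, cat, user = "u1") {
  data.table(timestamp = as.integer(ts), user_id = user, query_text = "q",
             category = cat)
}

test_that("window policy validates its inputs", {
  expect_error(window_policy(0), "positive")
  expect_error(window_policy(20, "sliding"))
  expect_equal(window_policy(20)$window_seconds, 1200)
})

test_that("queries within the window and of one type form one session", {
  s <- segment_sessions(cat_rec(c(0, 300), "informational"))
  expect_equal(nrow(s$sessions), 1L)
  expect_equal(s$sessions$length, 2L)
  expect_equal(s$sessions$session_type, "informational")
})

test_that("the duration cap splits at the window anchored on the first query", {
  # queries at minutes 0, 19, 21: third exceeds the 20-minute cap
  s <- segment_sessions(cat_rec(c(0, 19 * 60, 21 * 60), "informational"))
  expect_equal(s$sessions$length, c(2L, 1L))
  expect_equal(s$sessions$start, c(0L, 1260L))
  # under gap mode the same queries stay together (max gap 2 min)
  g <- segment_sessions(cat_rec(c(0, 19 * 60, 21 * 60), "informational"),
                        window_policy(20, "gap_threshold"))
  expect_equal(g$sessions$length, 3L)
})

test_that("an intent change forces a session boundary", {
  s <- segment_sessions(cat_rec(c(0, 60, 120),
                                c("informational", "navigational",
                                  "informational")))
  expect_equal(nrow(s$sessions), 3L)
  expect_equal(s$sessions$session_type,
               c("informational", "navigational", "informational"))
  # mixed acts as navigational for boundaries: nav->mixed is no boundary
  s2 <- segment_sessions(cat_rec(c(0, 60), c("navigational", "mixed")))
  expect_equal(nrow(s2$sessions), 1L)
  expect_equal(s2$sessions$session_type, "navigational")
})

test_that("invalid inputs are rejected; unsorted input is sorted, not an error", {
  expect_error(segment_sessions(cat_rec(c(-1, 5), "informational")),
               "negative")
  expect_error(segment_sessions(cat_rec(1, "empty_translation")),
               "empty_translation")
  shuffled <- cat_rec(c(500, 0, 250), "informational")
  s <- segment_sessions(shuffled)
  expect_equal(s$queries$timestamp, c(0L, 250L, 500L))
  expect_equal(nrow(s$sessions), 1L)
})

test_that("streaming segmentation equals the quadratic brute-force oracle", {
  set.seed(42)
  for (rep in 1:200) {
    log <- random_mini_log()
    mode <- sample(c("duration_cap", "gap_threshold"), 1L)
    win <- sample(c(5, 20, 60), 1L)
    s <- segment_sessions(log, window_policy(win, mode))
    q <- s$queries
    setorder(q, user_id, timestamp)
    expected <- q[, brute_session_ids(
      timestamp, ifelse(category == "informational", "i", "n"),
      win * 60, mode), by = user_id]$V1
    expect_equal(q$session_index, expected)
  }
})

test_that("concatenating a user's sessions reproduces the query sequence", {
  set.seed(43)
  for (rep in 1:25) {
    log <- random_mini_log(n_users = 4L)
    s <- segment_sessions(log)
    for (u in unique(log$user_id)) {
      orig <- log[user_id == u][order(timestamp)]
      got <- s$queries[user_id == u][order(session_index, timestamp)]
      expect_equal(got$timestamp, orig$timestamp)
      expect_equal(got$category, orig$category)
    }
    # no loss, no duplication
    expect_equal(nrow(s$queries), nrow(log))
    expect_equal(sum(s$sessions$length), nrow(log))
  }
})

test_that("window constraints hold inside every session", {
  set.seed(44)
  for (rep in 1:25) {
    log <- random_mini_log()
    d <- segment_sessions(log, window_policy(10, "duration_cap"))
    expect_true(all(d$sessions$end - d$sessions$start <= 600))
    g <- segment_sessions(log, window_policy(10, "gap_threshold"))
    gaps <- g$queries[, if (.N > 1L) max(diff(timestamp)) else 0L,
                      by = .(user_id, session_index)]$V1
    expect_true(all(gaps <= 600))
  }
})

test_that("enlarging the window never increases the session count", {
  set.seed(45)
  for (mode in c("duration_cap", "gap_threshold")) {
    for (rep in 1:10) {
      log <- random_mini_log()
      n_prev <- Inf
      for (win in c(2, 5, 10, 30, 120)) {
        n <- nrow(segment_sessions(log, window_policy(win, mode))$sessions)
        expect_lte(n, n_prev)
        n_prev <- n
      }
    }
  }
})

test_that("only informational sessions are retained for analysis", {
  nav <- segment_sessions(cat_rec(c(0, 10), "navigational"))
  expect_equal(nrow(informational_sessions(nav)$sessions), 0L)
  expect_equal(attr(informational_sessions(nav), "n_excluded"), 1L)

  mix <- segment_sessions(cat_rec(c(0, 2000, 4000),
                                  c("informational", "mixed",
                                    "informational")))
  kept <- informational_sessions(mix)
  expect_equal(kept$sessions$session_type,
               rep("informational", nrow(kept$sessions)))
  expect_true(!is.unsorted(kept$sessions$start))

  # conservation: a log with no navigational/mixed queries loses nothing
  cfg <- synth_config(n_users = 40, p_navigational_query = 0,
                      p_mixed_query = 0, p_malformed_record = 0, seed = 5)
  syn <- generate_log(cfg)
  res <- categorize_log(syn$records)
  seg <- segment_sessions(res$queries)
  expect_equal(nrow(informational_sessions(seg)$sessions),
               nrow(seg$sessions))
})
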