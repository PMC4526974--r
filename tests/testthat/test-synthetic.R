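test_that("generator configuration is validated", {
  expect_error(synth_config(fraction_experienced = 1.2), "probabilities")
  expect_error(synth_config(p_navigational_query = 0.7, p_mixed_query = 0.5),
               "<= 1")
  expect_error(synth_config(inter_session_gap = list(offset_s = 0,
                                                     mean_s = 100)),
               "above the window")
  expect_error(synth_config(intra_session_gap = list(mean_s = 10, min_s = 5,
                                                     max_s = 2)),
               "intra_session_gap")
})

test_that("a fixed seed reproduces the log byte for byte", {
  cfg <- synth_config(n_users = 60, tag_typo_rate = 0.1, seed = 77)
  a <- generate_log(cfg)
  b <- generate_log(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$truth$sessions, b$truth$sessions)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_query_log(a$records, f1)
  write_query_log(b$records, f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed changes the log
  c <- generate_log(synth_config(n_users = 60, tag_typo_rate = 0.1, seed = 78))
  expect_false(identical(a$records, c$records))
})

test_that("without experienced users or navigational traffic no system functions appear", {
  cfg <- synth_config(n_users = 120, fraction_experienced = 0,
                      p_navigational_query = 0, p_mixed_query = 0,
                      p_malformed_record = 0, seed = 3)
  syn <- generate_log(cfg)
  expect_false(any(grepl("[][]", syn$records$query_text)))
  flags <- query_uses_system_functions(syn$records$query_text)
  expect_false(any(flags$positive))
})

test_that("ground truth aligns with the emitted records line by line", {
  cfg <- synth_config(n_users = 80, seed = 21)
  syn <- generate_log(cfg)
  expect_equal(nrow(syn$records), nrow(syn$truth$records))
  expect_equal(syn$records$timestamp, syn$truth$records$timestamp)
  expect_equal(syn$records$user_id[!syn$truth$records$malformed],
               syn$truth$records$user_id[!syn$truth$records$malformed])
  expect_true(all(syn$records$timestamp >= 0 &
                    syn$records$timestamp < cfg$day_seconds))
  # per-session truth agrees with per-record truth
  agg <- syn$truth$records[!(malformed),
                           .N, by = .(user_id, true_session_index)]
  expect_equal(nrow(agg), nrow(syn$truth$sessions))
  expect_equal(sum(agg$N), syn$truth$sessions[, sum(length)])
})

test_that("pipeline sessions equal ground truth when gaps clear the window", {
  cfg <- synth_config(n_users = 150, seed = 31)
  syn <- generate_log(cfg)
  res <- categorize_log(clean_records(syn$records)$records)
  seg <- segment_sessions(res$queries)
  truth <- copy(syn$truth$sessions)
  truth[, type := ifelse(session_type == "informational", "informational",
                         "navigational")]
  setorder(truth, user_id, start)
  got <- seg$sessions[order(user_id, start)]
  expect_equal(nrow(got), nrow(truth))
  expect_equal(got$start, truth$start)
  expect_equal(got$end, truth$end)
  expect_equal(got$length, truth$length)
  expect_equal(got$session_type, truth$type)
})

test_that("tag corruption is seeded, bounded to one edit, and recoverable", {
  rec <- make_records(1:3, "u1",
                      c("asthma [mesh]", "smith [author]", "plain words"))
  none <- corrupt_tags(rec, 0)
  expect_identical(none$records, rec)
  expect_equal(nrow(none$edits), 0L)

  all_c <- corrupt_tags(rec, 1, seed = 4)
  expect_identical(corrupt_tags(rec, 1, seed = 4)$records, all_c$records)
  expect_equal(nrow(all_c$edits), 2L)  # the tagless record has nothing to corrupt
  for (i in seq_len(nrow(all_c$edits))) {
    expect_equal(osa_distance(all_c$edits$original[i],
                              all_c$edits$corrupted[i]), 1L)
  }
})

test_that("fuzzy extraction recovers at least 95% of corrupted tags", {
  cfg <- synth_config(n_users = 400, fraction_experienced = 1, p_tag_use = 1,
                      p_malformed_record = 0, tag_typo_rate = 1, seed = 8)
  syn <- generate_log(cfg)
  edits <- syn$truth$edits
  expect_gt(nrow(edits), 200L)
  lex <- default_lexicon()
  # oracle for the intended tag: direct lookup-table match on the original
  truth_canon <- lex$lookup$canonical[match(tolower(edits$original),
                                            lex$lookup$surface)]
  expect_false(anyNA(truth_canon))
  recovered <- vapply(seq_len(nrow(edits)), function(i) {
    occ <- extract_tags(paste0("x [", edits$corrupted[i], "]"), lex,
                        max_edit_distance = 2)
    identical(occ$canonical, truth_canon[i])
  }, logical(1L))
  expect_gte(mean(recovered), 0.95)
})

test_that("session-length distributions match their configured geometric means", {
  cfg <- synth_config(n_users = 4000, p_malformed_record = 0, seed = 16)
  syn <- generate_log(cfg)
  info <- syn$truth$sessions[session_type == "informational"]
  info[syn$truth$users, user_class := i.user_class, on = "user_id"]
  for (grp in c("experienced", "nonexperienced")) {
    p <- if (grp == "experienced") cfg$session_length$p_experienced
         else cfg$session_length$p_nonexperienced
    lens <- info[user_class == grp, length]
    expect_gt(length(lens), 150L)
    se <- sd(lens) / sqrt(length(lens))
    expect_lt(abs(mean(lens) - 1 / p), 3 * se)
  }
})
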