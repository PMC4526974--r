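test_that("alias families resolve to a single canonical tag", {
  lex <- default_lexicon()
  for (surf in c("Author Name", "Author", "AU Name", "Auth", "AU")) {
    occ <- extract_tags(paste0("smith [", surf, "]"), lex)
    expect_equal(occ$canonical, "Author")
    expect_true(occ$matched_via %in% c("exact", "alias"))
  }
  expect_equal(nrow(lex$entries), 48L)
})

test_that("lexicon construction enforces its invariants", {
  expect_error(build_lexicon(data.frame(
    canonical = c("Title", "Text Words"),
    intent = c("informational", "informational"),
    aliases = c("ti", "ti"))), "more than one")
  expect_error(build_lexicon(data.frame(
    canonical = "Title", intent = "topical", aliases = "")), "intent")
  expect_error(build_lexicon(data.frame(
    canonical = c("Title", "title"),
    intent = c("informational", "informational"),
    aliases = c("", ""))), "duplicate")
  # empty alias lists give a lexicon of canonical names only
  lex <- build_lexicon(data.frame(canonical = "Title",
                                  intent = "informational", aliases = ""))
  expect_equal(nrow(lex$lookup), 1L)
  expect_equal(lex$lookup$via, "exact")
})

test_that("bracketed tags are extracted with spans, in order, unknowns reported", {
  lex <- tiny_lexicon()
  q <- '"myocardial infarction" [Title] AND smith [au] OR x [zzqq]'
  occ <- extract_tags(q, lex)
  expect_equal(occ$canonical, c("Title", "Author", NA))
  expect_equal(occ$matched_via, c("exact", "alias", "unknown"))
  expect_true(all(diff(occ$start) > 0))
  # 0-based half-open span encloses the bracketed form
  for (i in seq_len(nrow(occ))) {
    expect_equal(substr(q, occ$start[i] + 1L, occ$end[i]),
                 paste0("[", occ$surface[i], "]"))
  }
  expect_equal(nrow(extract_tags("high blood pressure", lex)), 0L)
})

test_that("misspelled tags resolve by bounded edit distance", {
  occ <- extract_tags("smith [Atuhor]", max_edit_distance = 2)
  expect_equal(occ$canonical, "Author")
  expect_equal(occ$matched_via, "fuzzy")
  # short surfaces only get budget 1
  expect_equal(extract_tags("x [qz]", max_edit_distance = 2)$matched_via,
               "unknown")
})

test_that("fuzzy matching at distance 0 coincides with pure alias lookup", {
  lex <- default_lexicon()
  surfaces <- lex$lookup$surface
  set.seed(11)
  corrupt1 <- function(s) {
    i <- sample.int(nchar(s), 1L)
    paste0(substr(s, 1, i - 1), sample(letters, 1L), substr(s, i + 1, nchar(s)))
  }
  for (k in 1:200) {
    s <- sample(surfaces, 1L)
    cand <- if (runif(1) < 0.5) s else corrupt1(s)
    occ <- extract_tags(paste0("x [", cand, "]"), lex, max_edit_distance = 0)
    # oracle: direct lookup-table match on the normalized surface
    hit <- match(tolower(cand), surfaces)
    if (is.na(hit)) {
      expect_equal(occ$matched_via, "unknown")
      expect_true(is.na(occ$canonical))
    } else {
      expect_equal(occ$canonical, lex$lookup$canonical[hit])
    }
  }
})

test_that("edit distance counts transpositions and respects known values", {
  expect_equal(osa_distance("atuhor", "author"), 1L)
  expect_equal(osa_distance("author", "author"), 0L)
  expect_equal(osa_distance("auth", "author"), 2L)
  expect_equal(osa_distance("", "ab"), 2L)
  expect_equal(osa_distance("kitten", "sitting"), 3L)
})

test_that("quoted phrases and user-tagged segments are copied verbatim", {
  tq <- translate_query('"diabetes mellitus" [MeSH]')
  expect_identical(tq$translated_text, tq$original_text)
  expect_equal(tq$tags$origin, "user")
  expect_equal(tq$tags$canonical, "MeSH Terms")
  # property: quoted and tagged spans survive byte-identically
  set.seed(21)
  terms <- c("asthma", "hypertension", "bone scan")
  for (k in 1:25) {
    quoted <- sprintf('"%s"', sample(terms, 1))
    tagged <- sprintf("%s [ti]", sample(terms, 1))
    free <- sample(terms, 1)
    q <- paste(sample(c(quoted, tagged, free)), collapse = " AND ")
    out <- translate_query(q)$translated_text
    expect_true(grepl(quoted, out, fixed = TRUE))
    expect_true(grepl(tagged, out, fixed = TRUE))
  }
})

test_that("untagged terms are looked up MeSH -> journal -> author -> all fields", {
  maps <- term_maps(mesh_terms = "hypertension", journal_names = "lancet")
  # oracle: direct table lookup decides the tag
  expect_equal(translate_query("hypertension", maps = maps)$translated_text,
               "hypertension [MeSH Terms]")
  expect_equal(translate_query("lancet", maps = maps)$translated_text,
               "lancet [Journal]")
  expect_equal(translate_query("smith ab", maps = maps)$translated_text,
               "smith ab [Author]")
  expect_equal(translate_query("zeolite", maps = maps)$translated_text,
               "zeolite [All Fields]")
  tq <- translate_query("hypertension", maps = maps)
  expect_equal(tq$tags$origin, "translation")
})

test_that("queries with no searchable content get an empty translation", {
  for (q in c("...", "!!", "   ", "", "AND OR NOT")) {
    expect_equal(translate_query(q)$category, "empty_translation")
  }
  expect_error(categorize_query(translate_query("...")), "empty")
})

test_that("intent categorization follows the tag classes", {
  expect_equal(translate_query('"diabetes mellitus" [MeSH]')$category,
               "informational")
  expect_equal(translate_query("Yoo [author] AND Mosa [author]")$category,
               "navigational")
  # informational user tag + translation-added navigational tag -> mixed
  expect_equal(translate_query("asthma [ti] AND lancet")$category, "mixed")
  # an explicit user-added navigational tag overrides mixed
  expect_equal(translate_query("asthma [ti] AND smith [au]")$category,
               "navigational")
  # tagless non-empty content serves an information need
  expect_equal(translate_query("rare zeolite lung")$category, "informational")
})

test_that("categorization partitions every cleaned query", {
  set.seed(33)
  pool <- c('"diabetes mellitus" [MeSH]', "Yoo [author] AND Mosa [mesh]",
            "asthma [ti] AND lancet", "high blood pressure", "...",
            "nutrition*", "#1 AND hypertension", "smith [Atuhor]",
            "lancet", "smith ab", "x [zzqq]", "AND", '"flu"')
  cats <- vapply(pool, function(q) translate_query(q)$category, character(1))
  expect_true(all(cats %in% c("informational", "navigational", "mixed",
                              "empty_translation")))
  # bulk driver agrees with the per-query path and drops empty translations
  rec <- make_records(seq_along(pool), "u1", pool)
  res <- categorize_log(rec)
  expect_equal(res$n_empty_translation, sum(cats == "empty_translation"))
  expect_equal(res$queries$category,
               unname(cats[cats != "empty_translation"]))
  expect_equal(sum(res$category_counts) + res$n_empty_translation, nrow(rec))
})

test_that("extract_tags is idempotent on its own canonical surfaces", {
  lex <- default_lexicon()
  occ <- extract_tags("asthma [mh] AND smith [au]", lex)
  for (canon in occ$canonical) {
    again <- extract_tags(paste0("x [", canon, "]"), lex)
    expect_equal(again$canonical, canon)
    expect_equal(again$matched_via, "exact")
  }
})
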