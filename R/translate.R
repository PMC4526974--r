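#' Term maps for approximate automatic term mapping
#'
#' PubMed's Automatic Term Mapping (ATM) translates each untagged query term
#' against internal MeSH, journal, and author indexes. The production tables
#' are not available, so translation here is approximated by transparent
#' lookup tables: a MeSH term set, a journal-name set, and a token-shape rule
#' for author names ("surname initials"). Lookups are case-insensitive.
#' Empty sets are allowed — translation then degrades to all-fields tagging.
#'
#' @param mesh_terms character vector of MeSH-like terms.
#' @param journal_names character vector of journal names.
#' @param author_pattern regular expression (applied case-insensitively to
#'   the normalized term) recognising a surname-plus-initials shape.
#' @return an object of class `term_maps`.
#' @export
term_maps <- function(mesh_terms = character(),
                      journal_names = character(),
                      author_pattern = "^[a-z][a-z'.-]* [a-z]{1,2}$") {
  structure(list(
    mesh_terms = unique(normalize_surface(mesh_terms)),
    journal_names = unique(normalize_surface(journal_names)),
    author_pattern = author_pattern
  ), class = "term_maps")
}

#' @export
print.term_maps <- function(x, ...) {
  cat("<term_maps> ", length(x$mesh_terms), " MeSH terms, ",
      length(x$journal_names), " journals, author pattern '",
      x$author_pattern, "'\n", sep = "")
  invisible(x)
}

#' The shipped default term maps
#'
#' Loads the packaged MeSH-term and journal-name lists
#' (`inst/extdata/mesh_terms.txt`, `inst/extdata/journals.txt`). These are
#' small illustrative tables, not NLM's production indexes; they exist so the
#' translation stage has deterministic, auditable behaviour.
#'
#' @return a `term_maps` object (memoised for the session).
#' @export
default_term_maps <- function() {
  if (is.null(.pmlog_env$term_maps)) {
    mesh <- readLines(system.file("extdata", "mesh_terms.txt",
                                  package = "pmlog", mustWork = TRUE))
    jour <- readLines(system.file("extdata", "journals.txt",
                                  package = "pmlog", mustWork = TRUE))
    .pmlog_env$term_maps <- term_maps(mesh_terms = mesh, journal_names = jour)
  }
  .pmlog_env$term_maps
}

.connector_re <- "^(and|or|not)$"
.history_re <- "^#[0-9]+$"

# Parse one query into structural units. Returns a list with:
#   occ     - extract_tags() table (user-added tag occurrences)
#   chunks  - data.table(start, end, text, tagged, quoted) of content units
#             in 1-based inclusive character coordinates
#   has_content - TRUE if anything searchable remains
parse_query_units <- function(text, lexicon, max_edit_distance) {
  occ <- extract_tags(text, lexicon, max_edit_distance)
  spans <- data.table(s = integer(), e = integer(), kind = character())
  if (nrow(occ)) {
    spans <- rbind(spans, data.table(s = occ$start + 1L, e = occ$end,
                                     kind = "tag"))
  }
  qm <- gregexpr('"[^"]*"', text)[[1L]]
  if (qm[1L] != -1L) {
    qs <- data.table(s = as.integer(qm),
                     e = as.integer(qm) + attr(qm, "match.length") - 1L,
                     kind = "quote")
    # discard quote spans that collide with tag spans (malformed nesting)
    if (nrow(spans)) {
      clash <- vapply(seq_len(nrow(qs)), function(i) {
        any(qs$s[i] <= spans$e & qs$e[i] >= spans$s)
      }, logical(1L))
      qs <- qs[!clash]
    }
    spans <- rbind(spans, qs)
  }
  setorder(spans, s)
  # free-text pieces between special spans
  bounds <- c(0L, as.vector(rbind(spans$s, spans$e)), nchar(text) + 1L)
  pieces <- data.table(s = bounds[seq(1L, length(bounds), by = 2L)] + 1L,
                       e = bounds[seq(2L, length(bounds), by = 2L)] - 1L)
  pieces <- pieces[e >= s]
  chunks <- list()
  for (k in seq_len(nrow(pieces))) {
    piece <- substr(text, pieces$s[k], pieces$e[k])
    tml <- gregexpr("\\S+", piece)
    tm <- tml[[1L]]
    if (tm[1L] == -1L) next
    tok_s <- as.integer(tm) + pieces$s[k] - 1L
    tok_e <- tok_s + attr(tm, "match.length") - 1L
    tok <- regmatches(piece, tml)[[1L]]
    low <- tolower(tok)
    kind <- ifelse(grepl(.connector_re, low), "connector",
            ifelse(grepl(.history_re, low), "history",
            ifelse(grepl("^[^[:alnum:]\"#*]+$", tok), "punct", "word")))
    # group consecutive word tokens into one term chunk
    run <- cumsum(kind != "word" | c(TRUE, kind[-length(kind)] != "word"))
    for (r in unique(run[kind == "word"])) {
      sel <- which(run == r & kind == "word")
      chunks[[length(chunks) + 1L]] <- data.table(
        s = tok_s[sel[1L]], e = tok_e[sel[length(sel)]],
        text = substr(text, tok_s[sel[1L]], tok_e[sel[length(sel)]]),
        kind = "term")
    }
    for (i in which(kind == "history")) {
      chunks[[length(chunks) + 1L]] <- data.table(
        s = tok_s[i], e = tok_e[i], text = tok[i], kind = "history")
    }
  }
  quotes <- spans[kind == "quote"]
  if (nrow(quotes)) {
    chunks[[length(chunks) + 1L]] <- data.table(
      s = quotes$s, e = quotes$e,
      text = substr(rep(text, nrow(quotes)), quotes$s, quotes$e),
      kind = "quote")
  }
  chunks <- if (length(chunks)) rbindlist(chunks) else
    data.table(s = integer(), e = integer(), text = character(),
               kind = character())
  setorder(chunks, s)
  # a chunk is user-tagged when a tag span follows it across whitespace only
  chunks[, tagged := FALSE]
  if (nrow(occ) && nrow(chunks)) {
    for (i in seq_len(nrow(occ))) {
      ts <- occ$start[i] + 1L  # 1-based start of '['
      prev <- which(chunks$e < ts)
      if (!length(prev)) next
      p <- prev[length(prev)]
      between <- substr(text, chunks$e[p] + 1L, ts - 1L)
      if (grepl("^\\s*$", between)) set(chunks, i = p, j = "tagged", value = TRUE)
    }
  }
  list(occ = occ, chunks = chunks,
       has_content = nrow(chunks) > 0L || nrow(occ) > 0L)
}

# decide the ATM tag for one untagged term (normalized); returns canonical name
atm_lookup <- function(norm, maps) {
  if (endsWith(norm, "*")) return("All Fields")  # truncated stems search all fields
  if (norm %in% maps$mesh_terms) return("MeSH Terms")
  if (norm %in% maps$journal_names) return("Journal")
  if (grepl(maps$author_pattern, norm, ignore.case = TRUE)) return("Author")
  "All Fields"
}

#' Translate a query (approximate automatic term mapping)
#'
#' Mirrors the structure of PubMed's ATM: quoted phrases and segments already
#' carrying a user search tag are copied verbatim (never translated); each
#' remaining untagged term is looked up in order MeSH terms, then journal
#' names, then the author name-shape rule, and receives the corresponding
#' translation-added tag; terms matching nothing are tagged All Fields.
#' Boolean operators (AND/OR/NOT, case-insensitive) and search-history
#' references (`#N`) are treated as connectors, never looked up. A query with
#' no searchable content (e.g. only punctuation) yields
#' `category = "empty_translation"`.
#'
#' @param query_text a single query string.
#' @param lexicon a [build_lexicon()] result.
#' @param maps a [term_maps()] result.
#' @param max_edit_distance fuzzy budget for tag resolution, see
#'   [extract_tags()].
#' @return an object of class `translated_query`: a list with
#'   `original_text`, `translated_text`, `tags` (a `data.table` with the
#'   [extract_tags()] columns plus `origin` = `"user"` or `"translation"`;
#'   spans of translation-added tags are `NA`), and `category` (one of
#'   `informational`, `navigational`, `mixed`, `empty_translation`).
#' @export
#' @examples
#' translate_query('"diabetes mellitus" [MeSH]')
#' translate_query("hypertension")$category
translate_query <- function(query_text, lexicon = default_lexicon(),
                            maps = default_term_maps(),
                            max_edit_distance = 2L) {
  stopifnot(length(query_text) == 1L)
  units <- parse_query_units(query_text, lexicon, max_edit_distance)
  tags <- copy(units$occ)
  tags[, origin := rep("user", .N)]
  translated <- query_text
  if (!units$has_content) {
    tq <- list(original_text = query_text, translated_text = "",
               tags = tags, category = "empty_translation")
    class(tq) <- "translated_query"
    return(tq)
  }
  terms <- units$chunks[kind == "term" & !tagged]
  if (nrow(terms)) {
    added <- vapply(normalize_surface(terms$text), atm_lookup, character(1L),
                    maps = maps)
    idx <- match(added, lexicon$entries$canonical)
    tags <- rbind(tags, data.table(
      surface = added,
      canonical = added,
      intent = lexicon$entries$intent[idx],
      mesh = lexicon$entries$mesh[idx],
      matched_via = "exact",
      start = NA_integer_, end = NA_integer_,
      origin = "translation"))
    # splice "term [Tag]" replacements back into the original text
    out <- character(0L)
    pos <- 1L
    ord <- order(terms$s)
    for (i in ord) {
      out <- c(out, substr(query_text, pos, terms$s[i] - 1L),
               terms$text[i], " [", added[i], "]")
      pos <- terms$e[i] + 1L
    }
    out <- c(out, substr(query_text, pos, nchar(query_text)))
    translated <- paste(out, collapse = "")
  }
  tq <- list(original_text = query_text, translated_text = translated,
             tags = tags, category = NA_character_)
  tq$category <- categorize_tags(tags)
  class(tq) <- "translated_query"
  tq
}

#' @export
print.translated_query <- function(x, ...) {
  cat("<translated_query> [", x$category, "]\n", sep = "")
  cat("  original:   ", x$original_text, "\n", sep = "")
  cat("  translated: ", x$translated_text, "\n", sep = "")
  if (nrow(x$tags)) {
    cat("  tags: ", paste0(ifelse(is.na(x$tags$canonical), "?",
                                  x$tags$canonical),
                           " (", x$tags$origin, ")", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

# intent decision from a tag table (user + translation tags)
categorize_tags <- function(tags) {
  known <- tags[!is.na(canonical)]
  if (nrow(known) == 0L) return("informational")  # tagless content serves an information need
  has_info <- any(known$intent == "informational")
  has_nav <- any(known$intent == "navigational")
  if (has_info && !has_nav) return("informational")
  if (has_nav && !has_info) return("navigational")
  # both present: an explicit user-added navigational tag marks the query
  # navigational; otherwise it is mixed
  if (any(known$intent == "navigational" & known$origin == "user")) {
    return("navigational")
  }
  "mixed"
}

#' Categorize a translated query
#'
#' Applies the intent partition: only informational tags (or tagless but
#' non-empty content) make the query informational; only
#' navigational/citation tags make it navigational; both kinds make it mixed
#' unless the original query itself carries a user-added navigational tag,
#' which marks it navigational. Queries with empty translation must be
#' removed by the caller before this point.
#'
#' @param translated a [translate_query()] result.
#' @return one of `"informational"`, `"navigational"`, `"mixed"`.
#' @export
categorize_query <- function(translated) {
  stopifnot(inherits(translated, "translated_query"))
  if (identical(translated$category, "empty_translation")) {
    pm_stop("query has empty translation; exclude it before categorization")
  }
  categorize_tags(translated$tags)
}

#' Translate and categorize a whole log
#'
#' Vectorized driver over cleaned records: translates each distinct query
#' text once (results are shared across duplicate queries), attaches the
#' translation and category to every record, and separates out queries whose
#' translation is empty (they are removed from analysis, and counted).
#'
#' @param records cleaned records (`timestamp`, `user_id`, `query_text`).
#' @inheritParams translate_query
#' @return a list with `queries` (records plus `translated_text` and
#'   `category`, empty translations removed, input order preserved),
#'   `n_empty_translation`, and `category_counts` (named integer vector).
#' @export
categorize_log <- function(records, lexicon = default_lexicon(),
                           maps = default_term_maps(),
                           max_edit_distance = 2L) {
  records <- as.data.table(records)
  if (nrow(records) == 0L) {
    out <- copy(records)
    out[, `:=`(translated_text = character(), category = character())]
    return(list(queries = out, n_empty_translation = 0L,
                category_counts = c(informational = 0L, navigational = 0L,
                                    mixed = 0L)))
  }
  uq <- unique(records$query_text)
  tr <- lapply(uq, translate_query, lexicon = lexicon, maps = maps,
               max_edit_distance = max_edit_distance)
  cat_u <- vapply(tr, `[[`, character(1L), "category")
  txt_u <- vapply(tr, `[[`, character(1L), "translated_text")
  i <- match(records$query_text, uq)
  out <- copy(records)
  out[, translated_text := txt_u[i]]
  out[, category := cat_u[i]]
  n_empty <- sum(out$category == "empty_translation")
  out <- out[category != "empty_translation"]
  counts <- c(informational = sum(out$category == "informational"),
              navigational = sum(out$category == "navigational"),
              mixed = sum(out$category == "mixed"))
  list(queries = out, n_empty_translation = n_empty, category_counts = counts)
}
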