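#' Build a search-field-tag lexicon
#'
#' The lexicon holds the canonical PubMed-style search field tags, the intent
#' class of each tag (informational for topical fields such as MeSH, title,
#' text words; navigational for citation/identity fields such as author,
#' journal, volume, identifiers), an optional MeSH-family marker, and the
#' alias surface forms — documented and undocumented variants — under which a
#' tag is written between square brackets. All surfaces are matched on a
#' case-insensitive, whitespace-normalized form.
#'
#' Which of the tags count as navigational is configuration, not code: the
#' shipped default ([default_lexicon()]) classifies citation/identity fields
#' as navigational and topical fields as informational, and is documented as
#' an interpretation that can be overridden by supplying a different table.
#'
#' @param tags a data.frame with columns `canonical` (unique tag name),
#'   `intent` (`"informational"` or `"navigational"`), optional `mesh`
#'   (logical; tag belongs to the MeSH family), and `aliases` (comma-separated
#'   string or list of character vectors; may be empty).
#' @return an object of class `tag_lexicon`.
#' @export
#' @examples
#' lex <- build_lexicon(data.frame(
#'   canonical = c("Author", "Title"),
#'   intent = c("navigational", "informational"),
#'   aliases = c("au,auth", "ti")))
#' lex
build_lexicon <- function(tags) {
  tags <- as.data.table(tags)
  need <- c("canonical", "intent")
  if (!all(need %in% names(tags))) pm_stop("`tags` needs canonical and intent columns")
  if (!"mesh" %in% names(tags)) tags[, mesh := FALSE]
  if (!"aliases" %in% names(tags)) tags[, aliases := ""]
  tags[, mesh := as.logical(mesh)]
  if (any(is.na(tags$intent)) ||
      !all(tags$intent %in% c("informational", "navigational"))) {
    pm_stop("every canonical tag needs intent 'informational' or 'navigational'")
  }
  canon_norm <- normalize_surface(tags$canonical)
  if (anyDuplicated(canon_norm)) {
    pm_stop("duplicate canonical tag (case-insensitive): ",
            tags$canonical[duplicated(canon_norm)][1L])
  }
  alias_list <- if (is.list(tags$aliases)) {
    tags$aliases
  } else {
    strsplit(as.character(tags$aliases), ",", fixed = TRUE)
  }
  alias_list <- lapply(alias_list, function(a) unique(normalize_surface(a[trimws(a) != ""])))
  entries <- data.table(canonical = tags$canonical,
                        intent = tags$intent,
                        mesh = tags$mesh,
                        norm = canon_norm)
  lookup <- rbindlist(c(
    list(data.table(surface = canon_norm, canonical = tags$canonical,
                    via = "exact")),
    lapply(seq_len(nrow(tags)), function(i) {
      al <- setdiff(alias_list[[i]], canon_norm[i])
      if (!length(al)) return(NULL)
      data.table(surface = al, canonical = tags$canonical[i], via = "alias")
    })
  ))
  lookup <- unique(lookup, by = c("surface", "canonical"))
  dup <- lookup$surface[duplicated(lookup$surface)]
  if (length(dup)) {
    pm_stop("alias '", dup[1L], "' maps to more than one canonical tag")
  }
  lex <- structure(list(entries = entries, lookup = lookup), class = "tag_lexicon")
  attr(lex, "cache") <- new.env(parent = emptyenv())
  lex
}

#' @export
print.tag_lexicon <- function(x, ...) {
  cat("<tag_lexicon> ", nrow(x$entries), " canonical tags (",
      sum(x$entries$intent == "informational"), " informational, ",
      sum(x$entries$intent == "navigational"), " navigational), ",
      nrow(x$lookup), " surface forms\n", sep = "")
  invisible(x)
}

#' The shipped default tag lexicon
#'
#' Loads the packaged configuration of 48 PubMed search field tags with their
#' alias families and intent classes (see `inst/extdata/pubmed_field_tags.tsv`
#' in the source). The object is memoised for the session.
#'
#' @return a `tag_lexicon`.
#' @export
default_lexicon <- function() {
  if (is.null(.pmlog_env$lexicon)) {
    path <- system.file("extdata", "pubmed_field_tags.tsv", package = "pmlog",
                        mustWork = TRUE)
    tab <- fread(path, sep = "\t", header = TRUE, colClasses = "character")
    tab[, mesh := mesh == "TRUE"]
    .pmlog_env$lexicon <- build_lexicon(tab)
  }
  .pmlog_env$lexicon
}

# Resolve one normalized bracket surface against the lexicon.
# Order: exact canonical name, then alias, then fuzzy within the edit budget
# (<= 1 for surfaces shorter than 6 characters, <= 2 otherwise, both capped by
# max_edit_distance). Fuzzy ties: smallest distance, then lexicographically
# smallest canonical name. Returns list(canonical, via); canonical is NA for
# unresolvable surfaces.
resolve_tag_surface <- function(norm, lexicon, max_edit_distance) {
  cache <- attr(lexicon, "cache")
  key <- paste0(max_edit_distance, "\r", norm)
  if (!is.null(cache) && !is.null(hit <- cache[[key]])) return(hit)
  lk <- lexicon$lookup
  i <- which(lk$surface == norm)
  res <- if (length(i)) {
    list(canonical = lk$canonical[i[1L]], via = lk$via[i[1L]])
  } else {
    budget <- min(as.integer(max_edit_distance),
                  if (nchar(norm) < 6L) 1L else 2L)
    if (budget < 1L) {
      list(canonical = NA_character_, via = "unknown")
    } else {
      dists <- vapply(lk$surface, osa_distance, integer(1L), a = norm,
                      cap = budget)
      ok <- which(dists <= budget)
      if (!length(ok)) {
        list(canonical = NA_character_, via = "unknown")
      } else {
        best <- ok[dists[ok] == min(dists[ok])]
        cand <- sort(unique(lk$canonical[best]))
        list(canonical = cand[1L], via = "fuzzy")
      }
    }
  }
  if (!is.null(cache)) cache[[key]] <- res
  res
}

#' Extract search-field tags from query text
#'
#' Finds every bracketed substring in the query and resolves it against the
#' lexicon: exact canonical-name match first, then alias match, then fuzzy
#' match by restricted Damerau-Levenshtein distance within
#' `max_edit_distance` (further bounded to 1 for surfaces shorter than six
#' characters and 2 otherwise; fuzzy ties break to the smallest distance,
#' then the lexicographically smallest canonical name). Unresolvable
#' bracketed substrings are reported with `matched_via = "unknown"` rather
#' than dropped — they are data, not failures.
#'
#' @param query_text a single query string.
#' @param lexicon a [build_lexicon()] result; default [default_lexicon()].
#' @param max_edit_distance maximum edit distance for fuzzy tag resolution;
#'   `0` disables fuzzy matching (alias matching only).
#' @return a `data.table`, one row per bracketed occurrence in span order:
#'   `surface` (text between the brackets, as written), `canonical`
#'   (resolved tag or `NA`), `intent`, `mesh`, `matched_via`
#'   (`exact`/`alias`/`fuzzy`/`unknown`), `start`, `end` (0-based half-open
#'   character span of the bracketed form within the query).
#' @export
#' @examples
#' extract_tags('"myocardial infarction" [Title]')
#' extract_tags("smith [Atuhor]")  # fuzzy -> Author
extract_tags <- function(query_text, lexicon = default_lexicon(),
                         max_edit_distance = 2L) {
  stopifnot(length(query_text) == 1L, max_edit_distance >= 0)
  empty <- data.table(surface = character(), canonical = character(),
                      intent = character(), mesh = logical(),
                      matched_via = character(),
                      start = integer(), end = integer())
  if (is.na(query_text) || !nzchar(query_text)) return(empty)
  ml <- gregexpr("\\[[^][]*\\]", query_text)
  m <- ml[[1L]]
  if (m[1L] == -1L) return(empty)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  bracketed <- regmatches(query_text, ml)[[1L]]
  surface <- substr(bracketed, 2L, nchar(bracketed) - 1L)
  norm <- normalize_surface(surface)
  res <- lapply(norm, resolve_tag_surface, lexicon = lexicon,
                max_edit_distance = max_edit_distance)
  canonical <- vapply(res, `[[`, character(1L), "canonical")
  via <- vapply(res, `[[`, character(1L), "via")
  idx <- match(canonical, lexicon$entries$canonical)
  data.table(surface = surface,
             canonical = canonical,
             intent = lexicon$entries$intent[idx],
             mesh = !is.na(idx) & lexicon$entries$mesh[idx],
             matched_via = via,
             start = starts - 1L,
             end = starts - 1L + lens)
}
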