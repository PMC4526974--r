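`%||%` <- function(x, y) if (is.null(x)) y else x

#' Normalize a tag or term surface form
#'
#' Lower-cases, trims, and collapses internal whitespace. All lexicon and
#' term-map lookups operate on this normal form, which makes them
#' case-insensitive by construction.
#'
#' @param x character vector.
#' @return character vector of the same length.
#' @keywords internal
normalize_surface <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Restricted Damerau-Levenshtein (optimal string alignment) distance
#'
#' Edit distance counting substitutions, insertions, deletions and
#' transpositions of adjacent characters. Used to resolve misspelled
#' bracketed search-field tags (e.g. `[Atuhor]` -> Author) against the
#' lexicon's surface forms.
#'
#' @param a,b single strings.
#' @param cap optional early-exit bound: if the length difference alone
#'   exceeds `cap` the function returns `cap + 1` without running the DP.
#' @return non-negative integer distance.
#' @export
#' @examples
#' osa_distance("atuhor", "author")  # 1 (one transposition)
osa_distance <- function(a, b, cap = Inf) {
  stopifnot(length(a) == 1L, length(b) == 1L)
  na <- nchar(a); nb <- nchar(b)
  if (abs(na - nb) > cap) return(as.integer(min(cap + 1, .Machine$integer.max)))
  if (na == 0L) return(nb)
  if (nb == 0L) return(na)
  s <- strsplit(a, "", fixed = TRUE)[[1L]]
  t <- strsplit(b, "", fixed = TRUE)[[1L]]
  d <- matrix(0L, na + 1L, nb + 1L)
  d[, 1L] <- 0:na
  d[1L, ] <- 0:nb
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      cost <- if (s[i] == t[j]) 0L else 1L
      m <- min(d[i, j + 1L] + 1L,        # deletion
               d[i + 1L, j] + 1L,        # insertion
               d[i, j] + cost)           # substitution / match
      if (i > 1L && j > 1L && s[i] == t[j - 1L] && s[i - 1L] == t[j]) {
        m <- min(m, d[i - 1L, j - 1L] + 1L)  # transposition
      }
      d[i + 1L, j + 1L] <- m
    }
  }
  d[na + 1L, nb + 1L]
}

# round for reports while keeping full precision internally
round_pct <- function(x, digits = 2L) round(x, digits)

# stop with a consistent prefix
pm_stop <- function(...) stop(..., call. = FALSE)
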