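---
title: "Session analysis of PubMed-style query logs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Session analysis of PubMed-style query logs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmlog)
library(data.table)
```

## The analysis

PubMed is a field-oriented retrieval system: search terms can be restricted
to one of its database fields by a bracketed search field tag
(`"myocardial infarction" [Title]`), indexed under the MeSH controlled
vocabulary, truncated with a word-final wildcard (`nutrition*`), or combined
with earlier result sets through history references (`#1 AND hypertension`).
Because results are not relevance-ranked by default, fluent use of these
*system functions* is what distinguishes an experienced searcher from one
typing plain natural language.

This package reconstructs, from a raw one-day query log, how experienced and
nonexperienced searchers differ in how quickly they close an information
need. The unit of analysis is the *session*: a maximal run of one user's
same-intent queries inside a temporal window. The headline statistic is the
*decrease rate* from the length-1 baseline,

$$\mathrm{DR}(L) = 1 - \frac{N(L)}{N(1)},$$

where $N(L)$ is the number of a group's sessions containing exactly $L$
queries. A session of length 1 is the ideal retrieval — the first query
satisfied the need — so a steeper fall-off from the baseline indicates
faster success.

The pipeline has five stages, each an exported function:

1. **Cleaning** (`clean_records`): records with an empty user identifier, an
   identifier failing a validity predicate, or empty/whitespace-only query
   text are removed, each reason tallied. The default identifier predicate
   (non-empty printable ASCII without whitespace, length 1–64) is
   deliberately loose — only a handful of records in millions fail it — and
   is injectable because "unusual identifier" is a site-specific notion.
2. **Translation and categorization** (`translate_query`,
   `categorize_query`): an approximation of PubMed's Automatic Term Mapping
   assigns a search tag to every untagged term, and the combined user-added
   and translation-added tags decide the query's intent.
3. **Session segmentation** (`segment_sessions`): per user, time-sorted
   queries are split at temporal-window violations and at intent changes.
4. **Expertise classification** (`query_uses_system_functions`,
   `label_sessions`, `rollup_users`): a session is experienced when any of
   its queries uses a system function; users with at least one experienced
   session are experienced users.
5. **Statistics** (`queries_per_user`, `query_type_proportions`,
   `length_distribution`, `decrease_rate`, `compare_groups`).

`run_pipeline()` composes the stages, asserts conservation of record counts
at every boundary, and can serialise all tables deterministically.

## Query translation and intent

Intent is read off search tags. Tags are classified as *informational*
(topical fields: MeSH terms and subheadings, title, title/abstract, text
words, substances, all-fields, …) or *navigational* (citation/identity
fields: author variants, journal, volume, issue, pagination, dates,
identifiers, …). The shipped lexicon
(`system.file("extdata", "pubmed_field_tags.tsv", package = "pmlog")`)
carries 48 canonical tags, each with an alias family — documented short
codes and undocumented variants alike, since real logs write the same tag as
`[Author Name]`, `[Author]`, `[AU Name]`, `[Auth]` or `[AU]`. The
informational/navigational split of specific tags is not fixed by any
authoritative list; the shipped assignment is our interpretation, stored as
data precisely so it can be audited and overridden.

A query is then:

* **informational** if it carries only informational tags — or no tags at
  all, since plain keyword content still serves an information need;
* **navigational** if it carries only navigational tags;
* **mixed** when both kinds appear — *unless* the original query itself
  contains a user-written navigational tag, which we treat as an explicit
  navigational indication that overrides the mixed reading. The typical
  mixed query is therefore a user-tagged topic plus a term that translation
  maps onto a journal or author index;
* **empty translation** when nothing searchable remains (punctuation-only,
  connectors-only); such queries are dropped and counted.

Translation itself is a transparent approximation: quoted phrases and
already-tagged segments are copied byte-for-byte (they are never
translated), Boolean operators and history tokens are connectors, and each
remaining term is looked up in order MeSH terms → journal names → an
author name-shape rule, falling back to All Fields. The shipped term maps
are small illustrative tables, not production indexes; production term
mapping (phrase segmentation order, index coverage) is explicitly out of
scope because only the *tag classes* matter for intent, not retrieval-grade
translation. With empty term maps the stage degrades gracefully to
all-fields tagging, which leaves intent decisions to user-written tags.

### Misspelled tags

Logs contain misspelled tags (`[Atuhor]`) that the live system rejects but a
human reader resolves at a glance. We reproduce that resolution
deterministically: a bracketed surface that matches no canonical name or
alias is matched fuzzily under the restricted Damerau–Levenshtein distance
(substitution, insertion, deletion, adjacent transposition), with a budget
of 1 edit for surfaces shorter than six characters and 2 otherwise, capped
by the `max_edit_distance` argument. Ties break to the smallest distance,
then the lexicographically smallest canonical name — an arbitrary but
reproducible rule. With a budget of 0 the resolver collapses exactly onto
alias lookup, a property the test suite checks against a table-lookup
oracle. Unresolvable surfaces are reported as unknown, never dropped:
they are data.

## Session segmentation choices

Two readings of a "maximum window length" coexist in the log-analysis
literature, and both are implemented in `window_policy()`:

* `duration_cap` (default): a session may span at most `window_minutes`
  from its first query. This reading matches the observation that complete
  biomedical search tasks take roughly 14–17 minutes, which motivates the
  20-minute default.
* `gap_threshold`: the gap between consecutive queries may not exceed the
  window — the convention of classical web-log studies.

Independently of time, a change of query intent forces a boundary (a
*session shift*). We boundary on **any** type change, not only
informational→navigational: the motivating principle is that intent changed,
whichever direction. Mixed queries act as navigational both for boundaries
and for retention, because mixed intent is not purely informational and
mixed queries are excluded from the analysis anyway. Timestamp ties within
a user preserve input file order, which keeps segmentation deterministic.

The streaming segmenter is verified against an independent quadratic oracle
(repeatedly take the longest prefix that is a valid single session) on a
thousand random mini-logs per test run, alongside the structural
invariants: concatenating a user's sessions reproduces their query sequence
exactly; no session violates its window constraint; enlarging the window
never increases the session count.

## Expertise classification

The four indicator flags are always computed from the **original** query
text. This matters: translation adds a MeSH tag to any term found in the
MeSH map, so reading flags from translated text would mark lay queries like
`high blood pressure` as experienced. The canonical contrast —
`hypertension [MeSH]` experienced, `high blood pressure` nonexperienced even
though the two are synonymous — only holds on the raw text.

Dual-behaviour users (some sessions experienced, some not) are classed
experienced. Whether their *nonexperienced sessions* should also be counted
in the experienced group is genuinely ambiguous, so both policies exist:
`relabel` (default) moves all of an experienced user's sessions into the
experienced group; `keep` moves only the user classification. Session
totals are conserved under either policy, and neither is asserted as the
historically correct one.

## The synthetic-data generator

No public redistribution of the original log file is bundled; instead
`generate_log()` emits a full-day log whose statistical structure mirrors
what the analysis assumes, together with line-by-line ground truth. The
defaults were chosen once, as the study conditions, and are documented here
rather than tuned:

| parameter | default | rationale |
|---|---|---|
| `n_users` | 1000 (tests), 5000 (acceptance script) | desk-scale runs |
| `fraction_experienced` | 0.06 | experienced share of sessions near 6% |
| sessions/user | Poisson(0.8) + 1 | most users have one burst |
| info session length | geometric, p = 0.60 / 0.47 | the groups' length-1 shares (~60% vs ~47%) equal p under a geometric law |
| nav/mixed burst length | geometric, p = 0.8 | navigational lookups are short |
| intra-session gap | Exp(45 s) in [2, 120] s, compressed to ≤ 95% of the window | a session never straddles the window |
| inter-session gap | window + 300 s + Exp(1800 s) | support strictly above the window |
| `p_tag_use`/`p_truncation`/`p_history_ref` | 0.7 / 0.10 / 0.05 | yields a dual-behaviour user share near 1% |
| type mix | 0.69 / 0.26 / 0.05 | observed query-type proportions |
| `p_malformed_record` | 0.0271 | reproduces a ~2.64% removal rate with the observed composition of removal reasons |
| `tag_typo_rate` | 0 | see below |

Because informational session lengths are geometric, the model reproduces
the length-1 proportions and the qualitative decrease-rate ordering
(DR(2) ≈ 100·p, so the experienced group falls off faster), but **not** the
heavy upper tail of real session lengths — real logs contain sessions
hundreds of queries long, which a geometric law makes astronomically rare.
Group means in synthetic runs are therefore smaller than in real data, and
passing tests say nothing about tail behaviour.

Session types are drawn per session, but with probabilities reweighted by
the type's expected session length, so the configured
navigational/mixed/informational mix is achieved at the *query* level in
expectation. Timestamps are capped at one simulated day (86,400 s); a
user's sessions that would spill past midnight are dropped rather than
wrapped, so per-user session counts are bounded above by their drawn count.

Two generator choices deserve justification:

* **Inter-session gaps always clear the window.** With the gap support
  strictly above the window and intra-session spans compressed below it,
  the generator's session boundaries coincide exactly with what the
  segmenter must find. This makes boundary recovery a sharp test: any
  disagreement is a bug, not noise. Overlapping supports are rejected by
  `synth_config()` as a configuration error.
* **Typos are opt-in (`tag_typo_rate = 0` by default) and target word-like
  surfaces.** A single character edit in a two-letter code (`[mh]` →
  `[mj]`) produces a *different valid code*, not a recognisable
  misspelling — no resolver, human or mechanical, can recover the intent —
  so `corrupt_tags()` only edits surfaces of four or more characters.
  Corruption also interacts with categorization (a corrupted tag can
  legitimately resolve to a different intent class), so exact
  boundary-recovery guarantees are stated for clean tags, and typo recovery
  is measured separately against the generator's edit log (≥ 95% of
  corrupted tags must resolve to their original canonical tag at budget 2).

## Numerical and reporting conventions

Percentages are computed at full precision and rounded to two decimals only
in written reports. Summary statistics are computed on raw session lengths,
never on percentage tables; a single observation has standard deviation 0
by convention. Extreme outliers are retained in means and standard
deviations; `length_distribution()` merely flags lengths above a
configurable percentile. Decrease rates are not clamped: `N(L) > N(1)`
yields a negative rate, and an unobserved length yields 100%. No
significance testing is performed — group differences are reported
descriptively via `compare_groups()`.

All randomness flows through explicit integer seeds; identical
configuration and seed give byte-identical logs and byte-identical run
artifacts (the manifest deliberately contains no wall-clock timestamps).

## Problem sizes

The shipped test-suite runs use logs of 25–400 users (up to ~1,500 records)
for unit and property tests, 4,000–5,000 users (~15,000 records) for
parameter-recovery checks, and the acceptance script analyses a 5,000-user
synthetic day. These sizes were chosen so that recovery tolerances (±2
percentage points on the experienced-session fraction; 3 standard errors on
distribution means) are comfortably binding while a full run stays in the
tens of seconds on one core. The pipeline itself is linear in the number of
records — per-query translation is cached on distinct query strings — and
has been exercised on multi-hundred-thousand-record logs without
modification.

## Known limitations

* Term mapping is a lookup-table approximation; queries whose intent in the
  real system would come from index collisions (a topical word that is also
  a journal title) follow the shipped tables instead.
* The informational/navigational split of the 48 tags is an interpretation
  stored as configuration, not an authoritative list.
* Whether tagless natural-language queries were historically categorized
  from translation-added tags alone is implied rather than documented; this
  package does exactly that, and records the choice here.
* The generator models neither query reformulation semantics nor realistic
  biomedical language; its vocabulary lists exist to exercise the term maps,
  not to be linguistically representative.
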