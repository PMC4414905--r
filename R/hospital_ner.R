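# Hospital name extraction and normalization.
#
# Users write hospital names as acronyms, abbreviations, and misspellings.
# Mentions are resolved to canonical names by a stepwise procedure:
# (1) exact equality with a canonical name, (2) exact equality with any
# listed alias, (3) fuzzy matching by minimal Levenshtein distance to any
# alias, accepted only within a length-relative threshold. Candidate spans
# are token n-grams of the normalized message text; overlaps are resolved
# longest-match first.

#' Levenshtein edit distance
#'
#' Unit-cost insert/delete/substitute distance, vectorized elementwise with
#' recycling. Symmetric; satisfies identity and the triangle inequality.
#'
#' @param a,b character vectors (recycled to a common length).
#' @return integer vector of distances.
#' @export
#' @examples
#' edit_distance("kitten", "sitting")  # 3
edit_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  out <- integer(n)
  for (i in seq_len(n)) {
    out[i] <- as.integer(utils::adist(a[i], b[i]))
  }
  out
}

# Flattened (one row per alias) matching table for a hospital lexicon.
alias_table <- function(hospitals) {
  lens <- lengths(hospitals$aliases)
  at <- tibble(canonical_id = rep(hospitals$canonical_id, lens),
               region = rep(hospitals$region, lens),
               canonical_name = rep(hospitals$canonical_name, lens),
               alias = unlist(hospitals$aliases))
  at$alias_norm <- normalize_string(at$alias)
  at$is_canonical <- at$alias_norm == normalize_string(at$canonical_name)
  at <- at[!duplicated(paste(at$canonical_id, at$alias_norm, sep = "\r")), ]
  at$nchar_alias <- stri_length(at$alias_norm)
  at
}

# Tie-break among candidate alias rows: prefer the message's region (when
# known), then the longest alias, then the lexicographically smallest
# canonical_id. Returns a one-row slice.
pick_best_row <- function(rows, region = NULL) {
  if (!is.null(region)) {
    same <- rows$region == region
    if (any(same)) rows <- rows[same, , drop = FALSE]
  }
  ord <- order(-rows$nchar_alias, rows$canonical_id)
  rows[ord[1], , drop = FALSE]
}

match_one <- function(cand, at, region, max_rel_distance, dists = NULL) {
  # Step 1: exact equality with a canonical name.
  hit <- which(at$is_canonical & at$alias_norm == cand)
  if (length(hit)) {
    best <- pick_best_row(at[hit, ], region)
    return(list(canonical_id = best$canonical_id, match_step = "exact",
                distance = 0L, ambiguous = FALSE))
  }
  # Step 2: exact equality with any alias.
  hit <- which(at$alias_norm == cand)
  if (length(hit)) {
    best <- pick_best_row(at[hit, ], region)
    return(list(canonical_id = best$canonical_id, match_step = "alias",
                distance = 0L, ambiguous = FALSE))
  }
  # Step 3: fuzzy — minimal edit distance to any alias within its threshold.
  if (is.null(dists)) dists <- drop(utils::adist(cand, at$alias_norm))
  thr <- pmax(1L, floor(max_rel_distance * at$nchar_alias))
  ok <- dists <= thr
  if (!any(ok)) return(NULL)
  dmin <- min(dists[ok])
  rows <- at[ok & dists == dmin, , drop = FALSE]
  if (!is.null(region)) {
    same <- rows$region == region
    if (any(same)) rows <- rows[same, , drop = FALSE]
  }
  ambiguous <- length(unique(rows$canonical_id)) > 1L
  ord <- order(-rows$nchar_alias, rows$canonical_id)
  best <- rows[ord[1], , drop = FALSE]
  list(canonical_id = best$canonical_id, match_step = "fuzzy",
       distance = as.integer(dmin), ambiguous = ambiguous)
}

#' Resolve one candidate surface form to a canonical hospital
#'
#' Applies the stepwise normalization procedure: exact canonical-name match,
#' then alias-table lookup, then fuzzy matching by minimal edit distance to
#' any alias, accepted only if the distance is at most
#' `max(1, floor(max_rel_distance * nchar(alias)))`. The first step that
#' succeeds wins and is reported. Fuzzy ties are broken by smallest distance,
#' then same-region preference (when `region` is given), then longest alias,
#' then smallest canonical id; a fuzzy tie between distinct hospitals that
#' survives the region preference is flagged `ambiguous`.
#'
#' @param candidate a candidate surface form (normalized internally).
#' @param hospitals a `hospital_lexicon` tibble.
#' @param region optional region label of the containing message.
#' @param max_rel_distance fuzzy threshold as a fraction of alias length
#'   (default 0.25).
#' @return `NULL` for no match, else a list with `canonical_id`,
#'   `match_step` (`"exact"`, `"alias"` or `"fuzzy"`), `distance`, and
#'   `ambiguous`.
#' @export
match_hospital <- function(candidate, hospitals, region = NULL,
                           max_rel_distance = 0.25) {
  at <- alias_table(hospitals)
  match_one(normalize_string(candidate), at, region, max_rel_distance)
}

#' Extract hospital mentions from one message text
#'
#' Scans the normalized text for candidate spans (token n-grams up to
#' `max_ngram` tokens) and resolves each via the stepwise matcher. Overlapping
#' matches are resolved best-quality first: smallest edit distance, then
#' longest match, then leftmost.
#'
#' @param text raw message text.
#' @param hospitals a `hospital_lexicon` tibble.
#' @param region optional region label used for tie-breaking.
#' @param max_rel_distance fuzzy threshold fraction (default 0.25).
#' @param max_ngram maximum candidate length in tokens (default 5).
#' @param at precomputed [alias_table()] (internal optimization).
#' @return tibble with columns `surface` (normalized matched text), `start`,
#'   `end` (0-based half-open span in the normalized text), `canonical_id`,
#'   `match_step`, `distance`, `ambiguous`.
#' @export
extract_hospital_mentions <- function(text, hospitals, region = NULL,
                                      max_rel_distance = 0.25, max_ngram = 5,
                                      at = NULL) {
  if (is.null(at)) at <- alias_table(hospitals)
  empty <- tibble(surface = character(), start = integer(), end = integer(),
                  canonical_id = character(), match_step = character(),
                  distance = integer(), ambiguous = logical())
  norm <- normalize_text(text)
  toks <- tokenize(norm$text)
  ntok <- nrow(toks)
  if (ntok == 0L) return(empty)
  cand_list <- list()
  for (n in seq_len(min(max_ngram, ntok))) {
    i <- seq_len(ntok - n + 1L)
    j <- i + n - 1L
    cand_list[[n]] <- tibble(start = toks$start[i], end = toks$end[j])
  }
  cands <- bind_rows(cand_list)
  cands$cand <- stri_sub(norm$text, cands$start + 1L, cands$end)
  # Prune to fuzzy-plausible or exact-matchable candidates, then batch the
  # distance computation into a single adist() call.
  thr <- pmax(1L, floor(max_rel_distance * at$nchar_alias))
  lo <- min(at$nchar_alias - thr)
  hi <- max(at$nchar_alias + thr)
  clen <- stri_length(cands$cand)
  plaus <- (clen >= lo & clen <= hi) | cands$cand %in% at$alias_norm
  cands <- cands[plaus, , drop = FALSE]
  if (nrow(cands) == 0L) return(empty)
  D <- utils::adist(cands$cand, at$alias_norm)
  hits <- list()
  for (r in seq_len(nrow(cands))) {
    m <- match_one(cands$cand[r], at, region, max_rel_distance, dists = D[r, ])
    if (is.null(m)) next
    hits[[length(hits) + 1L]] <- tibble(
      surface = cands$cand[r], start = cands$start[r], end = cands$end[r],
      canonical_id = m$canonical_id, match_step = m$match_step,
      distance = m$distance, ambiguous = m$ambiguous)
  }
  if (!length(hits)) return(empty)
  h <- bind_rows(hits)
  # Overlap resolution: best match quality first (smallest edit distance),
  # then longest match, then leftmost. Distance precedes length so that a
  # verbatim alias keeps its exact span instead of being engulfed by a
  # fuzzily-matching longer n-gram around it.
  ord <- order(h$distance, -(h$end - h$start), h$start)
  h <- h[ord, , drop = FALSE]
  keep <- logical(nrow(h))
  ks <- integer(0); ke <- integer(0)
  for (r in seq_len(nrow(h))) {
    if (!any(h$start[r] < ke & h$end[r] > ks)) {
      keep[r] <- TRUE
      ks <- c(ks, h$start[r]); ke <- c(ke, h$end[r])
    }
  }
  h <- h[keep, , drop = FALSE]
  h[order(h$start), , drop = FALSE]
}

#' Extract hospital mentions for every message in a corpus
#'
#' @param messages messages tibble (`message_id`, `region`, `raw_text`, ...).
#' @param hospitals a `hospital_lexicon` tibble.
#' @param use_region use each message's region for same-region tie-breaking
#'   (default `TRUE`).
#' @param ... passed to [extract_hospital_mentions()].
#' @return mention tibble with a leading `message_id` column.
#' @export
extract_corpus_mentions <- function(messages, hospitals, use_region = TRUE, ...) {
  at <- alias_table(hospitals)
  res <- vector("list", nrow(messages))
  for (i in seq_len(nrow(messages))) {
    m <- extract_hospital_mentions(messages$raw_text[i], hospitals,
                                   region = if (use_region) messages$region[i],
                                   at = at, ...)
    if (nrow(m)) {
      m$message_id <- messages$message_id[i]
      res[[i]] <- m[, c("message_id", setdiff(names(m), "message_id"))]
    }
  }
  out <- bind_rows(res)
  if (is.null(out) || nrow(out) == 0L) {
    out <- tibble(message_id = character(), surface = character(),
                  start = integer(), end = integer(), canonical_id = character(),
                  match_step = character(), distance = integer(),
                  ambiguous = logical())
  }
  out
}

#' Filter messages to those with clear hospital mentions
#'
#' Retains messages that have at least one resolved mention and no ambiguity
#' flag. A message is ambiguous when some candidate span ties between two or
#' more distinct hospitals at minimal edit distance at the fuzzy step.
#'
#' @param messages messages tibble.
#' @param mentions mention tibble from [extract_corpus_mentions()].
#' @return the retained subset of `messages`, input order preserved.
#' @export
filter_messages <- function(messages, mentions) {
  if (nrow(mentions) == 0L) return(messages[0, , drop = FALSE])
  amb <- unique(mentions$message_id[mentions$ambiguous])
  ok <- setdiff(unique(mentions$message_id), amb)
  messages[messages$message_id %in% ok, , drop = FALSE]
}
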