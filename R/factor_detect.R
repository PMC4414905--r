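# Quality-factor detection: dictionary-based keyword matching per sentence.
#
# Matching is substring-at-token-boundary on normalized text (no stemming or
# lemmatization), mirroring the keyword-list mechanism; equivalents resolve
# to their owning lexicon entry, and overlapping matches go to the longest
# keyword first.

#' Detect quality-factor keyword mentions in one message
#'
#' Sentence-splits the normalized text, then matches factor-lexicon keys
#' (keywords and their equivalents) against token n-grams within each
#' sentence, longest-first and non-overlapping. Matches must align with token
#' boundaries; internal punctuation breaks a match naturally because the
#' candidate is compared as a literal substring.
#'
#' @param text raw message text.
#' @param factors a `factor_lexicon` tibble.
#' @param lookup precomputed [factor_lookup_table()] (internal optimization).
#' @return tibble with columns `sentence_index` (1-based), `start`, `end`
#'   (0-based half-open span in the normalized message text), `surface`,
#'   `keyword` (the owning entry's canonical keyword), `factor`,
#'   `subcategory`.
#' @export
detect_factor_mentions <- function(text, factors, lookup = NULL) {
  if (is.null(lookup)) lookup <- factor_lookup_table(factors)
  empty <- tibble(sentence_index = integer(), start = integer(), end = integer(),
                  surface = character(), keyword = character(),
                  factor = character(), subcategory = character())
  norm <- normalize_string(text)
  if (!nzchar(norm)) return(empty)
  sents <- split_sentences(norm)
  if (nrow(sents) == 0L) return(empty)
  max_n <- max(lookup$n_tokens)
  out <- list()
  for (j in seq_len(nrow(sents))) {
    toks <- tokenize(sents$sentence[j])
    ntok <- nrow(toks)
    if (ntok == 0L) next
    cand <- list()
    for (n in seq_len(min(max_n, ntok))) {
      i <- seq_len(ntok - n + 1L)
      cand[[n]] <- tibble(start = toks$start[i], end = toks$end[i + n - 1L])
    }
    cand <- bind_rows(cand)
    cand$surface <- stri_sub(sents$sentence[j], cand$start + 1L, cand$end)
    hit <- match(cand$surface, lookup$key)
    cand <- cand[!is.na(hit), , drop = FALSE]
    hit <- hit[!is.na(hit)]
    if (nrow(cand) == 0L) next
    ord <- order(-(cand$end - cand$start), cand$start)
    cand <- cand[ord, , drop = FALSE]
    hit <- hit[ord]
    keep <- logical(nrow(cand))
    ks <- integer(0); ke <- integer(0)
    for (r in seq_len(nrow(cand))) {
      if (!any(cand$start[r] < ke & cand$end[r] > ks)) {
        keep[r] <- TRUE
        ks <- c(ks, cand$start[r]); ke <- c(ke, cand$end[r])
      }
    }
    cand <- cand[keep, , drop = FALSE]
    hit <- hit[keep]
    if (nrow(cand) == 0L) next
    res <- tibble(sentence_index = j,
                  start = cand$start + sents$start[j],
                  end = cand$end + sents$start[j],
                  surface = cand$surface,
                  keyword = lookup$keyword[hit],
                  factor = lookup$factor[hit],
                  subcategory = lookup$subcategory[hit])
    out[[length(out) + 1L]] <- res[order(res$start), , drop = FALSE]
  }
  if (!length(out)) return(empty)
  bind_rows(out)
}

#' Detect factor mentions for every message in a corpus
#'
#' @param messages messages tibble.
#' @param factors a `factor_lexicon` tibble.
#' @return mention tibble with a leading `message_id` column.
#' @export
detect_corpus_factors <- function(messages, factors) {
  lookup <- factor_lookup_table(factors)
  res <- vector("list", nrow(messages))
  for (i in seq_len(nrow(messages))) {
    m <- detect_factor_mentions(messages$raw_text[i], factors, lookup = lookup)
    if (nrow(m)) {
      m$message_id <- messages$message_id[i]
      res[[i]] <- m[, c("message_id", setdiff(names(m), "message_id"))]
    }
  }
  out <- bind_rows(res)
  if (is.null(out) || nrow(out) == 0L) {
    out <- tibble(message_id = character(), sentence_index = integer(),
                  start = integer(), end = integer(), surface = character(),
                  keyword = character(), factor = character(),
                  subcategory = character())
  }
  out
}

#' Add grouping metadata to mention or instance tables
#'
#' Joins region and posted-at-derived `year` / `month` columns from the
#' messages tibble, so the result can be grouped by the analytics functions.
#'
#' @param mentions a tibble with a `message_id` column.
#' @param messages messages tibble with `region` and `posted_at`.
#' @return `mentions` with `region`, `year` (integer) and `month`
#'   (`"YYYY-MM"`) columns appended.
#' @export
enrich_mentions <- function(mentions, messages) {
  meta <- tibble(message_id = messages$message_id,
                 region = messages$region,
                 year = as.integer(substr(messages$posted_at, 1, 4)),
                 month = substr(messages$posted_at, 1, 7))
  left_join(mentions, meta, by = "message_id")
}

#' Count factor mentions by grouping keys
#'
#' Partitions the mentions by the requested keys and counts; the total over
#' all partitions always equals the number of mentions (conservation).
#'
#' @param mentions mention (or instance) tibble; must already carry the
#'   requested columns (see [enrich_mentions()] for region/time keys).
#' @param by subset of `region`, `year`, `month`, `factor`, `subcategory`,
#'   `canonical_id`.
#' @return tibble of the grouping columns plus `n`.
#' @export
count_factors <- function(mentions, by) {
  allowed <- c("region", "year", "month", "factor", "subcategory", "canonical_id")
  bad <- setdiff(by, allowed)
  if (length(bad)) {
    hm_abort(sprintf("unknown group key(s): %s (allowed: %s)",
                     paste(bad, collapse = ", "), paste(allowed, collapse = ", ")),
             class = "hospmine_usage_error")
  }
  missing <- setdiff(by, names(mentions))
  if (length(missing)) {
    hm_abort(sprintf("mentions table lacks column(s) %s; enrich_mentions() adds region/time keys",
                     paste(missing, collapse = ", ")),
             class = "hospmine_usage_error")
  }
  if (nrow(mentions) == 0L) {
    out <- mentions[, by, drop = FALSE]
    out$n <- integer(0)
    return(as_tibble(out))
  }
  count(mentions, across(all_of(by)), name = "n")
}
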