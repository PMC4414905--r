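# Results-style aggregations over polarized factor instances: factor share
# distributions by region/time, within-factor item shares, term-hospital
# co-occurrence in negatively opinionated threads, and the overall
# recommendation share.

# Instance filtering shared by the distribution functions. The default
# denominator is the classified (non-neutral) instances; include_neutral
# switches the neutral ones back in.
filter_instances <- function(instances, polarity = NULL, include_neutral = FALSE) {
  x <- instances
  if (!is.null(polarity)) {
    polarity <- match.arg(polarity, c("positive", "negative"))
    x <- x[to_binary(x$polarity) == polarity, , drop = FALSE]
  } else if (!include_neutral) {
    x <- x[x$polarity != "neutral", , drop = FALSE]
  }
  x
}

#' Factor share distribution by region and/or time
#'
#' Computes, within each group, the percentage share of each quality factor:
#' `share(factor | group) = 100 * count(factor, group) / count(group)`.
#' Shares within every group sum to 100. With `polarity = "negative"` the
#' distribution is taken over negatively polarized instances only, which
#' yields the yearly negative-attitude trend when grouped by year.
#'
#' @param instances polarized factor instances (see
#'   [assign_factor_polarity()]), enriched with any requested grouping
#'   columns (see [enrich_mentions()]).
#' @param by grouping columns (e.g. `"region"`, `"year"`, `c("year","month")`);
#'   empty for a single overall group.
#' @param polarity optional binary filter, `"positive"` or `"negative"`.
#' @param include_neutral include neutral instances in the denominator
#'   (default `FALSE`: the denominator is the classified, non-excluded
#'   instances).
#' @return tibble of the grouping columns plus `factor`, `n`, `share`;
#'   empty groups are omitted.
#' @export
factor_distribution <- function(instances, by = character(), polarity = NULL,
                                include_neutral = FALSE) {
  missing <- setdiff(by, names(instances))
  if (length(missing)) {
    hm_abort(sprintf("instances lack grouping column(s): %s",
                     paste(missing, collapse = ", ")),
             class = "hospmine_usage_error")
  }
  x <- filter_instances(instances, polarity, include_neutral)
  if (nrow(x) == 0L) {
    out <- x[, c(by, "factor"), drop = FALSE]
    out$n <- integer(0); out$share <- numeric(0)
    return(as_tibble(out))
  }
  tab <- count(x, across(all_of(c(by, "factor"))), name = "n")
  if (length(by)) {
    tab <- ungroup(mutate(group_by(tab, across(all_of(by))),
                          share = 100 * n / sum(n)))
  } else {
    tab$share <- 100 * tab$n / sum(tab$n)
  }
  tab
}

#' Ranked item shares within one quality factor
#'
#' Percentage of each keyword (or subcategory) among the instances of the
#' chosen factor, optionally restricted by polarity and year, in descending
#' share order. This is the drill-down view of what, concretely, drives a
#' factor's volume in a period.
#'
#' @param instances polarized factor instances (with `year` when filtering
#'   by year).
#' @param factor one of the six quality factor names.
#' @param polarity optional binary filter (`"positive"`/`"negative"`).
#' @param year optional year filter.
#' @param level `"keyword"` or `"subcategory"`.
#' @return tibble with columns `item`, `n`, `share`, sorted by descending
#'   share (ties by item for determinism).
#' @export
item_share <- function(instances, factor, polarity = NULL, year = NULL,
                       level = c("keyword", "subcategory")) {
  level <- match.arg(level)
  if (!factor %in% FACTOR_NAMES) {
    hm_abort(sprintf("unknown factor '%s' (expected one of: %s)", factor,
                     paste(FACTOR_NAMES, collapse = ", ")),
             class = "hospmine_usage_error")
  }
  x <- filter_instances(instances, polarity)
  x <- x[x$factor == factor, , drop = FALSE]
  if (!is.null(year)) {
    if (!"year" %in% names(x)) {
      hm_abort("instances lack a 'year' column; see enrich_mentions()",
               class = "hospmine_usage_error")
    }
    x <- x[x$year == year, , drop = FALSE]
  }
  if (nrow(x) == 0L) {
    return(tibble(item = character(), n = integer(), share = numeric()))
  }
  tab <- count(tibble(item = x[[level]]), item, name = "n")
  tab$share <- 100 * tab$n / sum(tab$n)
  tab[order(-tab$share, tab$item), , drop = FALSE]
}

# A thread is negatively opinionated iff at least one member message is
# binary-negative and none is binary-positive (messages without labels, e.g.
# filtered-out ones, do not count either way).
negative_threads <- function(threads, messages, labels) {
  lab <- left_join(messages[, c("message_id", "thread_id")], labels,
                   by = "message_id")
  agg <- summarise(group_by(lab, thread_id),
                   any_neg = any(binary == "negative", na.rm = TRUE),
                   any_pos = any(binary == "positive", na.rm = TRUE))
  agg$thread_id[agg$any_neg & !agg$any_pos]
}

#' Term-hospital co-occurrence in negatively opinionated threads
#'
#' For a query term, finds the negatively opinionated threads whose messages
#' contain the term (token-boundary match on normalized text) and reports,
#' for each hospital, the percentage of those threads that also mention the
#' hospital. A thread is negatively opinionated iff at least one member
#' message is binary-negative and none is binary-positive. The denominator
#' (number of negative threads containing the term) is recorded in the
#' `n_denominator` attribute.
#'
#' @param threads,messages corpus tibbles.
#' @param mentions hospital mention tibble (predicted or gold) with
#'   `message_id` and `canonical_id`.
#' @param labels classification labels from [classify_messages()].
#' @param term query term (one or more tokens).
#' @param include_titles also search thread titles for the term.
#' @return tibble with columns `term`, `canonical_id`, `n_threads`, `share`;
#'   empty when the term never occurs in a negative thread.
#' @export
cooccurrence <- function(threads, messages, mentions, labels, term,
                         include_titles = FALSE) {
  empty <- tibble(term = character(), canonical_id = character(),
                  n_threads = integer(), share = numeric())
  term_norm <- normalize_string(term)
  t_toks <- tokenize(term_norm)
  if (nrow(t_toks) == 0L) return(empty)
  k <- nrow(t_toks)
  has_term <- function(text) {
    s <- normalize_string(text)
    toks <- tokenize(s)
    n <- nrow(toks)
    if (n < k) return(FALSE)
    i <- seq_len(n - k + 1L)
    any(stri_sub(s, toks$start[i] + 1L, toks$end[i + k - 1L]) == term_norm)
  }
  msg_has <- vapply(messages$raw_text, has_term, logical(1), USE.NAMES = FALSE)
  term_threads <- unique(messages$thread_id[msg_has])
  if (include_titles) {
    title_has <- vapply(threads$title, has_term, logical(1), USE.NAMES = FALSE)
    term_threads <- union(term_threads, threads$thread_id[title_has])
  }
  neg <- negative_threads(threads, messages, labels)
  denom <- intersect(neg, term_threads)
  if (!length(denom)) return(empty)
  mt <- left_join(mentions[, c("message_id", "canonical_id")],
                  messages[, c("message_id", "thread_id")], by = "message_id")
  mt <- mt[mt$thread_id %in% denom, , drop = FALSE]
  if (nrow(mt) == 0L) return(empty)
  pair <- unique(mt[, c("canonical_id", "thread_id")])
  tab <- count(pair, canonical_id, name = "n_threads")
  tab <- tibble(term = term_norm, canonical_id = tab$canonical_id,
                n_threads = tab$n_threads,
                share = 100 * tab$n_threads / length(denom))
  tab <- tab[order(-tab$share, tab$canonical_id), , drop = FALSE]
  attr(tab, "n_denominator") <- length(denom)
  tab
}

#' Overall recommendation share
#'
#' `100 * positive instances / all classified instances` (all four classes in
#' the denominator), rounded half-up to two decimals.
#'
#' @param instances polarized factor instances.
#' @return percentage (scalar), `NA` for an empty instance table.
#' @export
recommendation_share <- function(instances) {
  if (nrow(instances) == 0L) return(NA_real_)
  round_half_up(100 * sum(instances$polarity == "positive") / nrow(instances), 2)
}
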