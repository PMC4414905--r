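# Recommendation type classification via sentiment-cue counting with
# mood-flow (sentence-sequence polarity) analysis.
#
# Each sentence gets a polarity: the sign of (positive cue count - negative
# cue count), with cues inside a negation window flipped. A message's
# four-class label follows from which polarities occur in its mood flow:
# positive (only +1 present), negative (only -1), bilateral (both), neutral
# (none). The binary reduction maps bilateral to negative — conflicting
# polarity in one message is treated as a non-recommendation — and neutral
# messages are excluded.

# Normalized cue lookup table: key, class (+1/-1), n_tokens.
cue_table <- function(sentiment) {
  keys <- c(normalize_string(sentiment$positive), normalize_string(sentiment$negative))
  cls <- c(rep(1L, length(sentiment$positive)), rep(-1L, length(sentiment$negative)))
  keep <- !duplicated(keys)
  tbl <- tibble(key = keys[keep], class = cls[keep])
  tbl$n_tokens <- stri_count_regex(tbl$key, "[\\p{L}\\p{N}]+")
  attr(tbl, "negation") <- normalize_string(sentiment$negation)
  tbl
}

#' Sentence polarity from sentiment cue counts
#'
#' Counts positive and negative cues in the sentence (token-boundary
#' matching, longest cue first, non-overlapping). A cue whose first token
#' falls within `negation_window` tokens after a negation marker has its sign
#' flipped. The polarity is the sign of the positive-minus-negative count, so
#' a tie yields 0 (a neutral sentence) — symmetric, with no positive bias.
#'
#' @param sentence sentence text (normalized internally).
#' @param sentiment a `sentiment_lexicon`.
#' @param negation_window number of tokens after a negation marker within
#'   which a cue flips sign (default 2).
#' @param cues precomputed internal cue table (optimization).
#' @return list with `polarity` (+1, 0 or -1), `n_pos`, `n_neg`.
#' @export
sentence_polarity <- function(sentence, sentiment, negation_window = 2,
                              cues = NULL) {
  if (is.null(cues)) cues <- cue_table(sentiment)
  s <- normalize_string(sentence)
  toks <- tokenize(s)
  ntok <- nrow(toks)
  if (ntok == 0L) return(list(polarity = 0L, n_pos = 0L, n_neg = 0L))
  max_n <- max(cues$n_tokens)
  cand <- list()
  for (n in seq_len(min(max_n, ntok))) {
    i <- seq_len(ntok - n + 1L)
    cand[[n]] <- tibble(tok_start = i, start = toks$start[i],
                        end = toks$end[i + n - 1L])
  }
  cand <- bind_rows(cand)
  cand$surface <- stri_sub(s, cand$start + 1L, cand$end)
  hit <- match(cand$surface, cues$key)
  cand <- cand[!is.na(hit), , drop = FALSE]
  hit <- hit[!is.na(hit)]
  if (nrow(cand) == 0L) return(list(polarity = 0L, n_pos = 0L, n_neg = 0L))
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
  cls <- cues$class[hit[keep]]
  markers <- attr(cues, "negation")
  if (length(markers)) {
    mpos <- which(toks$token %in% markers)
    if (length(mpos)) {
      for (r in seq_along(cls)) {
        gap <- cand$tok_start[r] - mpos
        if (any(gap >= 1 & gap <= negation_window)) cls[r] <- -cls[r]
      }
    }
  }
  n_pos <- sum(cls == 1L)
  n_neg <- sum(cls == -1L)
  list(polarity = as.integer(sign(n_pos - n_neg)), n_pos = n_pos, n_neg = n_neg)
}

#' Classify a message into a four-class recommendation type
#'
#' Computes the mood flow — the ordered sequence of per-sentence polarities —
#' and assigns the four-class label. In `"presence"` mode (default) the label
#' is positive when some sentence is +1 and none is -1, negative when the
#' reverse holds, bilateral when both polarities occur, and neutral when no
#' sentence is polarized. The alternative `"last"` mode lets the last
#' polarized sentence win (it never produces bilateral).
#'
#' @param text raw message text.
#' @param sentiment a `sentiment_lexicon`.
#' @param mode `"presence"` or `"last"`.
#' @param negation_window see [sentence_polarity()].
#' @param cues precomputed internal cue table (optimization).
#' @return list with `four_class`, `binary`, and integer vector
#'   `sentence_polarities`.
#' @export
mood_flow_classify <- function(text, sentiment, mode = c("presence", "last"),
                               negation_window = 2, cues = NULL) {
  mode <- match.arg(mode)
  if (is.null(cues)) cues <- cue_table(sentiment)
  sents <- split_sentences(normalize_string(text))
  pol <- integer(nrow(sents))
  for (j in seq_len(nrow(sents))) {
    pol[j] <- sentence_polarity(sents$sentence[j], negation_window = negation_window,
                                cues = cues)$polarity
  }
  has_pos <- any(pol == 1L)
  has_neg <- any(pol == -1L)
  four_class <- if (mode == "presence") {
    if (has_pos && has_neg) "bilateral"
    else if (has_pos) "positive"
    else if (has_neg) "negative"
    else "neutral"
  } else {
    nz <- pol[pol != 0L]
    if (!length(nz)) "neutral" else if (nz[length(nz)] == 1L) "positive" else "negative"
  }
  list(four_class = four_class, binary = to_binary(four_class),
       sentence_polarities = pol)
}

#' Reduce a four-class label to a binary recommendation
#'
#' positive -> positive; negative -> negative; bilateral -> negative (a
#' message where positive and negative sentiment coexist is counted as a
#' non-recommendation); neutral -> excluded.
#'
#' @param four_class character vector of four-class labels.
#' @return character vector in `positive`/`negative`/`excluded`.
#' @export
to_binary <- function(four_class) {
  map <- c(positive = "positive", negative = "negative",
           bilateral = "negative", neutral = "excluded")
  bad <- setdiff(unique(four_class), names(map))
  if (length(bad)) {
    hm_abort(sprintf("unknown four-class label(s): %s", paste(bad, collapse = ", ")),
             class = "hospmine_usage_error")
  }
  unname(map[four_class])
}

#' Classify every message in a corpus
#'
#' @param messages messages tibble.
#' @param sentiment a `sentiment_lexicon`.
#' @param mode,negation_window see [mood_flow_classify()].
#' @return tibble with `message_id`, `four_class`, `binary`,
#'   `polarity_string` (e.g. `"+0-"`), and list-column `sentence_polarities`.
#' @export
classify_messages <- function(messages, sentiment, mode = "presence",
                              negation_window = 2) {
  cues <- cue_table(sentiment)
  res <- vector("list", nrow(messages))
  sym <- c(`-1` = "-", `0` = "0", `1` = "+")
  for (i in seq_len(nrow(messages))) {
    cl <- mood_flow_classify(messages$raw_text[i], mode = mode,
                             negation_window = negation_window, cues = cues)
    res[[i]] <- tibble(message_id = messages$message_id[i],
                       four_class = cl$four_class,
                       binary = cl$binary,
                       polarity_string = paste(sym[as.character(cl$sentence_polarities)],
                                               collapse = ""),
                       sentence_polarities = list(cl$sentence_polarities))
  }
  out <- bind_rows(res)
  if (is.null(out) || nrow(out) == 0L) {
    out <- tibble(message_id = character(), four_class = character(),
                  binary = character(), polarity_string = character(),
                  sentence_polarities = list())
  }
  out
}

#' Assign recommendation polarity to factor mentions
#'
#' Every factor mention in a classified message receives exactly one
#' polarity: that of its containing sentence when the sentence is polarized,
#' otherwise the message's four-class label (sentence-first,
#' message-fallback inheritance).
#'
#' @param factor_mentions mention tibble from [detect_corpus_factors()].
#' @param labels label tibble from [classify_messages()].
#' @return the mentions with `polarity` (a four-class value), `four_class`
#'   and `binary` (message-level) columns appended.
#' @export
assign_factor_polarity <- function(factor_mentions, labels) {
  if (nrow(factor_mentions) == 0L) {
    out <- factor_mentions
    out$polarity <- character(0)
    out$four_class <- character(0)
    out$binary <- character(0)
    return(out)
  }
  idx <- match(factor_mentions$message_id, labels$message_id)
  if (anyNA(idx)) {
    hm_abort("factor mention references a message without a classification label",
             class = "hospmine_validation_error")
  }
  polarity <- character(nrow(factor_mentions))
  for (r in seq_len(nrow(factor_mentions))) {
    pols <- labels$sentence_polarities[[idx[r]]]
    j <- factor_mentions$sentence_index[r]
    sp <- if (!is.na(j) && j >= 1 && j <= length(pols)) pols[j] else 0L
    polarity[r] <- if (sp == 1L) "positive" else if (sp == -1L) "negative"
                   else labels$four_class[idx[r]]
  }
  out <- factor_mentions
  out$polarity <- polarity
  out$four_class <- labels$four_class[idx]
  out$binary <- labels$binary[idx]
  out
}
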