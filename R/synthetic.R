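# Seeded synthetic corpus generator with gold labels.
#
# Emulates the statistical structure the pipeline consumes — threads of short
# messages with region/month metadata, hospital mentions written as (possibly
# typo-corrupted) aliases, planted quality-factor keywords, and sentiment
# cues consistent with a drawn four-class polarity — not linguistic realism.
# Messages are assembled from lowercase token slots so the raw text equals
# its normalized form and every planted span is known exactly.

default_vocab <- function() {
  c("toddler", "fever", "cough", "sniffles", "vaccine", "syrup", "stroller",
    "diaper", "naptime", "playground", "morning", "evening", "weekend",
    "yesterday", "neighbor", "question", "answer", "sharing", "asked",
    "visited", "daughter", "son", "teething", "checkup", "rash", "sleepy",
    "crying", "milk", "bottle", "snack", "outing", "picnic", "lullaby",
    "blanket", "mittens", "booties")
}

# draw one element of x uniformly (safe for length-1 vectors)
sample1 <- function(x, prob = NULL) {
  x[sample.int(length(x), 1L, prob = prob)]
}

#' Synthetic corpus generator configuration
#'
#' Defaults encode the corpus shape this package targets: six regions, a mean
#' of 5.59 messages per thread, per-factor keyword-planting probability
#' 0.0334 (so about 18.45% of messages contain at least one factor keyword),
#' and a four-class polarity mixture of 36% positive, 5% negative, 3%
#' bilateral (negative plus bilateral being the 8% non-recommending share)
#' and 56% neutral, over the 2007-04 to 2013-05 posting window. The typo
#' model corrupts a planted alias with probability `typo_rate` by at most
#' `max_typo_ops` character edits.
#'
#' @param seed integer seed; fully determines the generated corpus.
#' @param regions region labels; threads are spread evenly across them.
#' @param n_threads threads generated per region.
#' @param messages_per_thread_mean mean thread size (1 + Poisson(mean - 1)).
#' @param sentences_range integer c(min, max) sentences per message;
#'   bilateral messages need at least 2.
#' @param words_range integer c(min, max) filler words per sentence.
#' @param hospital_mention_prob probability a message mentions a hospital
#'   (ignored when `hospital_weights` is given).
#' @param hospital_weights optional named probabilities (by canonical_id) for
#'   a per-message hospital draw; may sum to less than 1, the remainder being
#'   no mention.
#' @param typo_rate probability a planted alias is corrupted.
#' @param max_typo_ops maximum character edits per corrupted alias.
#' @param factor_probs named per-factor planting probabilities.
#' @param keyword_weights optional named list `factor -> named weights` for
#'   choosing which keyword of a factor to plant (default uniform).
#' @param polarity_mix named four-class mixture summing to 1.
#' @param vocab filler word vocabulary (must be collision-free with the
#'   lexicons for the noise-free closure property to hold).
#' @param extra_tokens words planted once in every message (e.g. a
#'   co-occurrence study term).
#' @param date_range c(first, last) year-month (`"YYYY-MM"`); thread months
#'   are drawn uniformly from this window.
#' @return a validated `generator_config` list.
#' @export
generator_config <- function(seed = 1,
                             regions = c("Seoul", "Daegu", "Busan", "Daejeon",
                                         "Incheon", "Gwangju"),
                             n_threads = 20,
                             messages_per_thread_mean = 5.59,
                             sentences_range = c(1, 4),
                             words_range = c(2, 4),
                             hospital_mention_prob = 0.9,
                             hospital_weights = NULL,
                             typo_rate = 0.1,
                             max_typo_ops = 1,
                             factor_probs = stats::setNames(rep(0.0334, 6), FACTOR_NAMES),
                             keyword_weights = NULL,
                             polarity_mix = c(positive = 0.36, neutral = 0.56,
                                              bilateral = 0.03, negative = 0.05),
                             vocab = default_vocab(),
                             extra_tokens = character(0),
                             date_range = c("2007-04", "2013-05")) {
  cfg <- list(seed = as.integer(seed), regions = regions, n_threads = n_threads,
              messages_per_thread_mean = messages_per_thread_mean,
              sentences_range = as.integer(sentences_range),
              words_range = as.integer(words_range),
              hospital_mention_prob = hospital_mention_prob,
              hospital_weights = hospital_weights,
              typo_rate = typo_rate, max_typo_ops = as.integer(max_typo_ops),
              factor_probs = factor_probs, keyword_weights = keyword_weights,
              polarity_mix = polarity_mix, vocab = vocab,
              extra_tokens = extra_tokens, date_range = date_range)
  probs <- c(cfg$hospital_mention_prob, cfg$typo_rate, cfg$factor_probs,
             cfg$polarity_mix, cfg$hospital_weights)
  if (any(probs < 0 | probs > 1)) {
    hm_abort("generator_config: probabilities must lie in [0, 1]",
             class = "hospmine_validation_error")
  }
  if (!setequal(names(cfg$polarity_mix),
                c("positive", "neutral", "bilateral", "negative")) ||
      abs(sum(cfg$polarity_mix) - 1) > 1e-8) {
    hm_abort("generator_config: polarity_mix must name the four classes and sum to 1",
             class = "hospmine_validation_error")
  }
  if (!is.null(cfg$hospital_weights) && sum(cfg$hospital_weights) > 1 + 1e-8) {
    hm_abort("generator_config: hospital_weights must sum to at most 1",
             class = "hospmine_validation_error")
  }
  if (cfg$messages_per_thread_mean < 1) {
    hm_abort("generator_config: messages_per_thread_mean must be >= 1",
             class = "hospmine_validation_error")
  }
  if (cfg$polarity_mix[["bilateral"]] > 0 && cfg$sentences_range[2] < 2) {
    hm_abort("generator_config: bilateral messages need at least 2 sentences; raise sentences_range",
             class = "hospmine_validation_error")
  }
  bad <- setdiff(names(cfg$factor_probs), FACTOR_NAMES)
  if (length(bad)) {
    hm_abort(sprintf("generator_config: unknown factor(s) in factor_probs: %s",
                     paste(bad, collapse = ", ")),
             class = "hospmine_validation_error")
  }
  structure(cfg, class = "generator_config")
}

#' Apply exactly n random character edits to an alias
#'
#' Edits (insert, delete, substitute) touch lowercase letters only and never
#' create, remove or duplicate spaces, so the corrupted surface stays in
#' normalized form. The realized edit distance to the original is at most
#' `n_ops` (edits can cancel).
#'
#' @param alias a normalized alias string.
#' @param n_ops number of edits (0 returns the alias unchanged).
#' @param alphabet characters available for insertion/substitution.
#' @return the corrupted surface form.
#' @export
corrupt_alias <- function(alias, n_ops, alphabet = letters) {
  stopifnot(n_ops >= 0)
  s <- strsplit(alias, "", fixed = TRUE)[[1]]
  for (k in seq_len(n_ops)) {
    nonspace <- which(s != " ")
    # deleting a letter from a 1-letter word would strand a space; forbid it
    word_id <- cumsum(s == " ")
    word_len <- table(word_id[s != " "])
    deletable <- nonspace[word_len[as.character(word_id[nonspace])] >= 2]
    op <- sample1(c("insert", "delete", "substitute"))
    if (op == "delete" && !length(deletable)) op <- "substitute"
    if (op == "insert") {
      pos <- sample1(0:length(s))
      s <- append(s, sample1(alphabet), after = pos)
    } else if (op == "delete") {
      s <- s[-sample1(deletable)]
    } else {
      pos <- sample1(nonspace)
      s[pos] <- sample1(setdiff(alphabet, s[pos]))
    }
  }
  paste(s, collapse = "")
}

#' Generate a gold-labeled synthetic corpus
#'
#' Deterministic given `config$seed`. Messages are assembled from sentence
#' templates: filler words from the vocabulary, an optional hospital alias
#' (drawn from the lexicon, then corrupted at the typo rate), planted factor
#' keywords, and sentiment cues consistent with the drawn four-class label
#' (bilateral messages get one positive and one negative sentence). The gold
#' record carries every planted hospital mention (with span and corruption
#' log), factor mention, per-sentence polarities, labels, and the polarized
#' factor instances implied by the sentence-first inheritance rule.
#'
#' @param config a [generator_config()].
#' @param hospitals,factors,sentiment lexicons to plant from; default the
#'   packaged stand-ins from [example_lexicons()].
#' @return list with `threads`, `messages`,
#'   `gold = list(hospital_mentions, factor_mentions, labels, instances)`,
#'   and the `config`.
#' @export
generate_corpus <- function(config, hospitals = NULL, factors = NULL,
                            sentiment = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(hospitals) || is.null(factors) || is.null(sentiment)) {
    lex <- example_lexicons()
    hospitals <- hospitals %||% lex$hospitals
    factors <- factors %||% lex$factors
    sentiment <- sentiment %||% lex$sentiment
  }
  if (!is.null(config$hospital_weights)) {
    bad <- setdiff(names(config$hospital_weights), hospitals$canonical_id)
    if (length(bad)) {
      hm_abort(sprintf("hospital_weights name unknown hospital(s): %s",
                       paste(bad, collapse = ", ")),
               class = "hospmine_validation_error")
    }
  }
  months <- month_seq(config$date_range[1], config$date_range[2])
  pos_cues <- normalize_string(sentiment$positive)
  neg_cues <- normalize_string(sentiment$negative)
  alias_norm <- lapply(hospitals$aliases, normalize_string)
  withr::with_seed(config$seed, {
    threads <- list(); messages <- list()
    g_hosp <- list(); g_fact <- list(); g_lab <- list()
    mid <- 0L; tid <- 0L
    for (region in config$regions) {
      region_rows <- which(hospitals$region == region)
      if (!length(region_rows)) region_rows <- seq_len(nrow(hospitals))
      for (t in seq_len(config$n_threads)) {
        tid <- tid + 1L
        thread_id <- sprintf("t%05d", tid)
        month <- sample1(months)
        title <- paste(sample(config$vocab, 3, replace = TRUE), collapse = " ")
        n_msg <- 1L + stats::rpois(1, config$messages_per_thread_mean - 1)
        msg_ids <- character(n_msg)
        for (m in seq_len(n_msg)) {
          mid <- mid + 1L
          message_id <- sprintf("m%06d", mid)
          msg_ids[m] <- message_id
          built <- build_message(config, hospitals, factors, region_rows,
                                 pos_cues, neg_cues, alias_norm)
          messages[[mid]] <- tibble(message_id = message_id,
                                    thread_id = thread_id, region = region,
                                    posted_at = paste0(month, "-01"),
                                    raw_text = built$text)
          if (nrow(built$hosp)) {
            built$hosp$message_id <- message_id
            g_hosp[[length(g_hosp) + 1L]] <- built$hosp
          }
          if (nrow(built$fact)) {
            built$fact$message_id <- message_id
            g_fact[[length(g_fact) + 1L]] <- built$fact
          }
          g_lab[[mid]] <- tibble(message_id = message_id,
                                 four_class = built$four_class,
                                 binary = to_binary(built$four_class),
                                 sentence_polarities = list(built$pol))
        }
        threads[[tid]] <- tibble(thread_id = thread_id, title = title,
                                 region = region, message_ids = list(msg_ids))
      }
    }
    threads <- bind_rows(threads)
    messages <- bind_rows(messages)
    labels <- bind_rows(g_lab)
    hosp <- if (length(g_hosp)) bind_rows(g_hosp) else
      tibble(message_id = character(), canonical_id = character(),
             alias = character(), surface = character(), start = integer(),
             end = integer(), typo = logical(), n_ops = integer())
    fact <- if (length(g_fact)) bind_rows(g_fact) else
      tibble(message_id = character(), sentence_index = integer(),
             start = integer(), end = integer(), surface = character(),
             keyword = character(), factor = character(),
             subcategory = character())
    front <- function(df) df[, c("message_id", setdiff(names(df), "message_id"))]
    hosp <- front(hosp); fact <- front(fact)
    instances <- assign_factor_polarity(fact, labels)
    list(threads = threads, messages = messages,
         gold = list(hospital_mentions = hosp, factor_mentions = fact,
                     labels = labels, instances = instances),
         config = config)
  })
}

month_seq <- function(from, to) {
  f <- as.integer(strsplit(from, "-", fixed = TRUE)[[1]])
  t <- as.integer(strsplit(to, "-", fixed = TRUE)[[1]])
  idx <- seq(f[1] * 12L + f[2] - 1L, t[1] * 12L + t[2] - 1L)
  sprintf("%04d-%02d", idx %/% 12L, idx %% 12L + 1L)
}

# Assemble one message from annotated token slots; returns text, gold
# hospital/factor rows (without message_id), four_class, sentence polarities.
build_message <- function(config, hospitals, factors, region_rows,
                          pos_cues, neg_cues, alias_norm) {
  four_class <- sample1(names(config$polarity_mix), prob = config$polarity_mix)
  smin <- config$sentences_range[1]; smax <- config$sentences_range[2]
  if (four_class == "bilateral") smin <- max(2L, smin)
  ns <- sample1(smin:smax)
  slots <- lapply(seq_len(ns), function(j) {
    lapply(sample(config$vocab, sample1(config$words_range[1]:config$words_range[2]),
                  replace = TRUE),
           function(w) list(text = w, tag = "filler"))
  })
  ins <- function(j, entry) {
    slots[[j]] <<- append(slots[[j]], list(entry),
                          after = sample1(0:length(slots[[j]])))
  }
  # hospital mention
  hrow <- NA_integer_
  if (!is.null(config$hospital_weights)) {
    w <- config$hospital_weights
    pick <- sample1(c(names(w), ".none"), prob = c(w, max(0, 1 - sum(w))))
    if (pick != ".none") hrow <- match(pick, hospitals$canonical_id)
  } else if (stats::runif(1) < config$hospital_mention_prob) {
    hrow <- sample1(region_rows)
  }
  if (!is.na(hrow)) {
    alias <- sample1(alias_norm[[hrow]])
    typo <- stats::runif(1) < config$typo_rate && config$max_typo_ops > 0
    n_ops <- if (typo) sample1(seq_len(config$max_typo_ops)) else 0L
    surface <- if (typo) corrupt_alias(alias, n_ops) else alias
    ins(sample1(seq_len(ns)),
        list(text = surface, tag = "hospital",
             meta = list(canonical_id = hospitals$canonical_id[hrow],
                         alias = alias, typo = typo, n_ops = as.integer(n_ops))))
  }
  # factor keywords
  for (f in names(config$factor_probs)) {
    p <- config$factor_probs[[f]]
    if (p <= 0 || stats::runif(1) >= p) next
    rows <- which(factors$factor == f)
    if (!length(rows)) next
    w <- NULL
    if (!is.null(config$keyword_weights[[f]])) {
      w <- config$keyword_weights[[f]][factors$keyword[rows]]
      w[is.na(w)] <- 0
    }
    r <- sample1(rows, prob = w)
    ins(sample1(seq_len(ns)),
        list(text = normalize_string(factors$keyword[r]), tag = "factor",
             meta = list(keyword = factors$keyword[r], factor = f,
                         subcategory = factors$subcategory[r])))
  }
  # sentiment cues consistent with the drawn class
  pol <- integer(ns)
  if (four_class == "positive") {
    j <- sample1(seq_len(ns)); pol[j] <- 1L
    ins(j, list(text = sample1(pos_cues), tag = "cue"))
  } else if (four_class == "negative") {
    j <- sample1(seq_len(ns)); pol[j] <- -1L
    ins(j, list(text = sample1(neg_cues), tag = "cue"))
  } else if (four_class == "bilateral") {
    jj <- sample(seq_len(ns), 2)
    pol[jj[1]] <- 1L; pol[jj[2]] <- -1L
    ins(jj[1], list(text = sample1(pos_cues), tag = "cue"))
    ins(jj[2], list(text = sample1(neg_cues), tag = "cue"))
  }
  for (w in config$extra_tokens) {
    ins(sample1(seq_len(ns)), list(text = normalize_string(w), tag = "extra"))
  }
  # assemble text and spans: slots joined by spaces, "." closing each sentence
  hosp <- list(); fact <- list()
  pieces <- character(ns)
  pos <- 0L
  for (j in seq_len(ns)) {
    texts <- vapply(slots[[j]], `[[`, "", "text")
    pieces[j] <- paste0(paste(texts, collapse = " "), ".")
    for (k in seq_along(slots[[j]])) {
      e <- slots[[j]][[k]]
      start <- pos; end <- pos + stri_length(e$text)
      if (identical(e$tag, "hospital")) {
        hosp[[length(hosp) + 1L]] <- tibble(
          canonical_id = e$meta$canonical_id, alias = e$meta$alias,
          surface = e$text, start = start, end = end,
          typo = e$meta$typo, n_ops = e$meta$n_ops)
      } else if (identical(e$tag, "factor")) {
        fact[[length(fact) + 1L]] <- tibble(
          sentence_index = j, start = start, end = end, surface = e$text,
          keyword = e$meta$keyword, factor = e$meta$factor,
          subcategory = e$meta$subcategory)
      }
      pos <- end + 1L
    }
    pos <- pos + 1L  # "." plus the joining space consumed one extra char
  }
  list(text = paste(pieces, collapse = " "),
       hosp = if (length(hosp)) bind_rows(hosp) else
         tibble(canonical_id = character(), alias = character(),
                surface = character(), start = integer(), end = integer(),
                typo = logical(), n_ops = integer()),
       fact = if (length(fact)) bind_rows(fact) else
         tibble(sentence_index = integer(), start = integer(), end = integer(),
                surface = character(), keyword = character(),
                factor = character(), subcategory = character()),
       four_class = four_class, pol = pol)
}
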