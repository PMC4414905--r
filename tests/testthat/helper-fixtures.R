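# In-code mini lexicons and corpora for unit tests.

mini_hospitals <- function() {
  validate_hospital_lexicon(tibble::tibble(
    canonical_id = c("A1", "A2", "A3"),
    canonical_name = c("Sunshine Pediatric", "Moonrise Kids Hospital",
                       "Riverside Child Clinic"),
    region = c("Seoul", "Busan", "Seoul"),
    aliases = list("sp clinic", "moonrise kids", "riverside child")))
}

mini_factors <- function() {
  validate_factor_lexicon(tibble::tibble(
    keyword = c("waiting time", "waiting", "parking", "famous"),
    factor = c("process", "process", "environment", "popularity"),
    subcategory = c("f15", "f16", "f20", "e6"),
    equivalents = list(c("queue", "wait"), character(0), character(0),
                       character(0))))
}

mini_sentiment <- function() {
  sentiment_lexicon(positive = c("good", "recommend"),
                    negative = c("bad", "terrible"),
                    negation = "not")
}

# A two-thread / five-message corpus with hand-known structure.
mini_corpus <- function() {
  threads <- tibble::tibble(
    thread_id = c("t1", "t2"),
    title = c("clinic question", "kids talk"),
    region = c("Seoul", "Busan"),
    message_ids = list(c("m1", "m2", "m3"), c("m4", "m5")))
  messages <- tibble::tibble(
    message_id = c("m1", "m2", "m3", "m4", "m5"),
    thread_id = c("t1", "t1", "t1", "t2", "t2"),
    region = c("Seoul", "Seoul", "Seoul", "Busan", "Busan"),
    posted_at = c("2009-03-01", "2009-03-01", "2009-04-01",
                  "2010-01-01", "2010-01-01"),
    raw_text = c("we visited sp clinic. good overall.",
                 "waiting time was terrible.",
                 "",
                 "moonrise kids felt good. parking was bad.",
                 "no hospital mentioned here."))
  list(threads = threads, messages = messages)
}

# Swap the positive and negative cue sets, keeping negation markers.
swap_sentiment <- function(sentiment) {
  sentiment_lexicon(positive = sentiment$negative,
                    negative = sentiment$positive,
                    negation = sentiment$negation)
}
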