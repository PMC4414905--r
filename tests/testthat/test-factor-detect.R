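test_that("factor keywords are detected per sentence, longest match first", {
  fac <- mini_factors()
  one <- detect_factor_mentions("the parking was easy to find.", fac)
  expect_equal(nrow(one), 1L)
  expect_equal(one$factor, "environment")
  expect_equal(one$subcategory, "f20")
  expect_equal(one$sentence_index, 1L)

  expect_equal(nrow(detect_factor_mentions("", fac)), 0L)

  # "waiting" and "waiting time" overlap: only the longer keyword matches
  over <- detect_factor_mentions("the waiting time was endless", fac)
  expect_equal(over$keyword, "waiting time")
  expect_equal(over$subcategory, "f15")
  # hand enumeration: the alternative matching would be "waiting" (f16) alone
  alone <- detect_factor_mentions("the waiting was endless", fac)
  expect_equal(alone$keyword, "waiting")

  # equivalents resolve to the owning entry
  eq <- detect_factor_mentions("the queue moved fast", fac)
  expect_equal(eq$keyword, "waiting time")
  expect_equal(eq$surface, "queue")
})

test_that("matches align with token boundaries and spans index the message", {
  fac <- mini_factors()
  # embedded in a longer token: no match
  expect_equal(nrow(detect_factor_mentions("reparking is not a word", fac)), 0L)
  m <- detect_factor_mentions("Parking was FINE. famous spot.", fac)
  norm <- normalize_string("Parking was FINE. famous spot.")
  expect_equal(substring(norm, m$start + 1, m$end), m$surface)
  expect_equal(m$sentence_index, c(1L, 2L))
})

test_that("concatenating two messages shifts mentions without changing them", {
  fac <- mini_factors()
  t1 <- "parking was easy. famous place."
  t2 <- "the waiting time was long."
  m1 <- detect_factor_mentions(t1, fac)
  m2 <- detect_factor_mentions(t2, fac)
  both <- detect_factor_mentions(paste(t1, t2), fac)
  expect_equal(nrow(both), nrow(m1) + nrow(m2))
  shift_chars <- nchar(t1) + 1L
  shift_sents <- nrow(split_sentences(t1))
  expect_equal(both$start, c(m1$start, m2$start + shift_chars))
  expect_equal(both$sentence_index, c(m1$sentence_index,
                                      m2$sentence_index + shift_sents))
  expect_equal(both$keyword, c(m1$keyword, m2$keyword))
})

test_that("factor counts partition exactly and conserve the total", {
  gen <- generate_corpus(generator_config(
    seed = 9, n_threads = 4,
    factor_probs = stats::setNames(rep(0.5, 6),
                                   c("service", "professionalism", "process",
                                     "environment", "impression", "popularity"))))
  lex <- example_lexicons()
  mentions <- detect_corpus_factors(gen$messages, lex$factors)
  expect_gt(nrow(mentions), 0)
  enriched <- enrich_mentions(mentions, gen$messages)
  for (by in list("factor", "subcategory", c("region", "factor"),
                  c("year", "month"))) {
    tab <- count_factors(enriched, by)
    expect_equal(sum(tab$n), nrow(mentions))
  }
  # detection equals the generator's planted gold at (message, factor) level
  expect_setequal(paste(mentions$message_id, mentions$factor,
                        mentions$subcategory),
                  paste(gen$gold$factor_mentions$message_id,
                        gen$gold$factor_mentions$factor,
                        gen$gold$factor_mentions$subcategory))
  # determinism: detection is a pure function of its inputs
  expect_identical(mentions, detect_corpus_factors(gen$messages, lex$factors))
})

test_that("count_factors rejects unknown or missing grouping keys", {
  fac <- mini_factors()
  m <- detect_factor_mentions("parking again", fac)
  m$message_id <- "m1"
  expect_error(count_factors(m, "flavor"), "unknown group key",
               class = "hospmine_usage_error")
  expect_error(count_factors(m, "region"), "enrich",
               class = "hospmine_usage_error")
  empty <- m[0, ]
  expect_equal(nrow(count_factors(empty, "factor")), 0L)
})
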