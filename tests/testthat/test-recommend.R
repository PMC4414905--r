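test_that("sentence polarity is the sign of the cue count difference", {
  sen <- mini_sentiment()
  expect_equal(sentence_polarity("good and good again", sen)$polarity, 1L)
  expect_equal(sentence_polarity("nothing emotional here", sen)$polarity, 0L)
  tie <- sentence_polarity("good but terrible", sen)
  expect_equal(tie$polarity, 0L)
  expect_equal(tie$n_pos, 1L)
  expect_equal(tie$n_neg, 1L)
  # negation window flips a cue within 2 tokens after the marker
  expect_equal(sentence_polarity("not good", sen)$polarity, -1L)
  expect_equal(sentence_polarity("not so good", sen)$polarity, -1L)
  expect_equal(sentence_polarity("not so very good", sen)$polarity, 1L)
})

test_that("mood flow assigns the four-class label from polarity presence", {
  sen <- mini_sentiment()
  expect_equal(mood_flow_classify("good start. good end.", sen)$four_class,
               "positive")
  bil <- mood_flow_classify("good start. terrible end.", sen)
  expect_equal(bil$four_class, "bilateral")
  expect_equal(bil$sentence_polarities, c(1L, -1L))
  expect_equal(mood_flow_classify("plain words only.", sen)$four_class, "neutral")
  expect_equal(mood_flow_classify("terrible. bad.", sen)$four_class, "negative")
  # last-polarized-sentence-wins mode never yields bilateral
  expect_equal(mood_flow_classify("good start. terrible end.", sen,
                                  mode = "last")$four_class, "negative")
  expect_equal(mood_flow_classify("terrible start. good end.", sen,
                                  mode = "last")$four_class, "positive")
})

test_that("binary reduction maps bilateral to negative and neutral to excluded", {
  expect_equal(to_binary(c("positive", "negative", "bilateral", "neutral")),
               c("positive", "negative", "negative", "excluded"))
  expect_error(to_binary("mixed"), class = "hospmine_usage_error")
})

test_that("factor mentions inherit sentence polarity, falling back to the message", {
  fac <- mini_factors()
  sen <- mini_sentiment()
  msgs <- tibble::tibble(
    message_id = "m1", thread_id = "t1", region = "Seoul",
    posted_at = "2009-01-01",
    raw_text = "parking was good. waiting time was terrible. famous place.")
  labels <- classify_messages(msgs, sen)
  expect_equal(labels$four_class, "bilateral")
  mentions <- detect_corpus_factors(msgs, fac)
  inst <- assign_factor_polarity(mentions, labels)
  expect_equal(inst$polarity[inst$keyword == "parking"], "positive")
  expect_equal(inst$polarity[inst$keyword == "waiting time"], "negative")
  # the unpolarized third sentence falls back to the message label
  expect_equal(inst$polarity[inst$keyword == "famous"], "bilateral")
  # all-positive message: every mention positive
  msgs2 <- msgs
  msgs2$raw_text <- "parking was good. famous and good. queue fine, good."
  inst2 <- assign_factor_polarity(detect_corpus_factors(msgs2, fac),
                                  classify_messages(msgs2, sen))
  expect_equal(nrow(inst2), 3L)
  expect_true(all(inst2$polarity == "positive"))
})

test_that("classification equals generator gold on noise-free corpora", {
  gen <- generate_corpus(generator_config(seed = 21, n_threads = 4, typo_rate = 0))
  lex <- example_lexicons()
  labels <- classify_messages(gen$messages, lex$sentiment)
  gold <- gen$gold$labels
  expect_equal(labels$four_class[match(gold$message_id, labels$message_id)],
               gold$four_class)
  inst <- assign_factor_polarity(detect_corpus_factors(gen$messages, lex$factors),
                                 labels)
  gold_inst <- gen$gold$instances
  expect_setequal(paste(inst$message_id, inst$keyword, inst$polarity),
                  paste(gold_inst$message_id, gold_inst$keyword,
                        gold_inst$polarity))
})

test_that("swapping the cue sets mirrors labels and cue-free sentences are inert", {
  lex <- example_lexicons()
  gen <- generate_corpus(generator_config(seed = 8, n_threads = 2))
  labels <- classify_messages(gen$messages, lex$sentiment)
  swapped <- classify_messages(gen$messages, swap_sentiment(lex$sentiment))
  map <- c(positive = "negative", negative = "positive",
           neutral = "neutral", bilateral = "bilateral")
  expect_equal(swapped$four_class, unname(map[labels$four_class]))
  # appending a cue-free sentence never changes the four-class label
  for (i in sample(seq_len(nrow(gen$messages)), 25)) {
    txt <- paste(gen$messages$raw_text[i], "sleepy toddler naptime.")
    expect_equal(mood_flow_classify(txt, lex$sentiment)$four_class,
                 labels$four_class[i])
  }
})
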