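test_that("edit distance matches its definition and metric properties", {
  expect_equal(edit_distance("a", "a"), 0L)
  expect_equal(edit_distance("", "abc"), 3L)
  expect_equal(edit_distance("kitten", "sitting"), 3L)
  expect_equal(edit_distance("kitten", "sitting"), lev_oracle("kitten", "sitting"))
  set.seed(3)
  pool <- all_strings(c("a", "b", "c"), 4)
  for (k in 1:80) {
    x <- sample(pool, 3)
    dxy <- edit_distance(x[1], x[2])
    expect_equal(dxy, edit_distance(x[2], x[1]))                  # symmetry
    expect_equal(dxy, lev_oracle(x[1], x[2]))                     # oracle
    expect_true(dxy <= edit_distance(x[1], x[3]) + edit_distance(x[3], x[2]))
    expect_equal(edit_distance(x[1], x[1]), 0L)                   # identity
  }
})

test_that("stepwise matching tries exact, then alias, then bounded fuzzy", {
  hosp <- mini_hospitals()
  ex <- match_hospital("sunshine pediatric", hosp)
  expect_equal(ex[c("canonical_id", "match_step", "distance")],
               list(canonical_id = "A1", match_step = "exact", distance = 0L))
  al <- match_hospital("SP  Clinic", hosp)
  expect_equal(al$canonical_id, "A1")
  expect_equal(al$match_step, "alias")
  fz <- match_hospital("moonrise kidz", hosp)
  expect_equal(fz$canonical_id, "A2")
  expect_equal(fz$match_step, "fuzzy")
  expect_equal(fz$distance, 1L)
  # the fuzzy distance is the brute-force minimum over all aliases
  aliases <- normalize_string(unlist(hosp$aliases))
  expect_equal(fz$distance, min(vapply(aliases, lev_oracle, 0L, a = "moonrise kidz")))
  expect_null(match_hospital("totally unrelated text", hosp))
})

test_that("fuzzy ties mark ambiguity unless the region preference resolves them", {
  twins <- validate_hospital_lexicon(tibble::tibble(
    canonical_id = c("B1", "B2"),
    canonical_name = c("Abcd Clinic", "Abce Clinic"),
    region = c("Seoul", "Busan"),
    aliases = list(character(0), character(0))))
  tie <- match_hospital("abcf clinic", twins)
  expect_true(tie$ambiguous)
  expect_equal(tie$distance, 1L)
  resolved <- match_hospital("abcf clinic", twins, region = "Seoul")
  expect_false(resolved$ambiguous)
  expect_equal(resolved$canonical_id, "B1")
})

test_that("mention extraction finds planted aliases with exact spans", {
  hosp <- mini_hospitals()
  m <- extract_hospital_mentions("we liked sp clinic a lot", hosp)
  expect_equal(nrow(m), 1L)
  expect_equal(m$canonical_id, "A1")
  expect_equal(m$surface, "sp clinic")
  expect_equal(substr("we liked sp clinic a lot", m$start + 1, m$end), "sp clinic")
  expect_equal(nrow(extract_hospital_mentions("weather was fine today", hosp)), 0L)
  # two clean aliases plus one 1-edit typo, one per sentence
  txt <- "sp clinic was fine. we saw riverside child. moonrise kidz was ok."
  m3 <- extract_hospital_mentions(txt, hosp)
  expect_equal(nrow(m3), 3L)
  expect_setequal(m3$canonical_id, c("A1", "A2", "A3"))
  expect_equal(m3$match_step[m3$canonical_id == "A2"], "fuzzy")
  expect_equal(m3$distance[m3$canonical_id == "A2"], 1L)
  expect_equal(m3$distance[m3$canonical_id != "A2"], c(0L, 0L))
})

test_that("message filtering keeps unambiguous mentions and drops the rest", {
  hosp <- mini_hospitals()
  twins <- validate_hospital_lexicon(tibble::tibble(
    canonical_id = c("B1", "B2"),
    canonical_name = c("Abcd Clinic", "Abce Clinic"),
    region = c("Seoul", "Seoul"),
    aliases = list(character(0), character(0))))
  msgs <- tibble::tibble(
    message_id = c("m1", "m2", "m3"),
    thread_id = "t1", region = "Seoul", posted_at = "2009-01-01",
    raw_text = c("sp clinic was fine", "nothing to see", "abcf clinic here"))
  both <- validate_hospital_lexicon(tibble::tibble(
    canonical_id = c(hosp$canonical_id, twins$canonical_id),
    canonical_name = c(hosp$canonical_name, twins$canonical_name),
    region = c(hosp$region, twins$region),
    aliases = c(hosp$aliases, twins$aliases)))
  mentions <- extract_corpus_mentions(msgs, both, use_region = FALSE)
  kept <- filter_messages(msgs, mentions)
  expect_equal(kept$message_id, "m1")
  expect_true(any(mentions$ambiguous[mentions$message_id == "m3"]))
})

test_that("extraction is perfect on a noise-free synthetic corpus", {
  gen <- generate_corpus(generator_config(seed = 5, n_threads = 3, typo_rate = 0))
  lex <- example_lexicons()
  mentions <- extract_corpus_mentions(gen$messages, lex$hospitals)
  pred <- unique(paste(mentions$message_id, mentions$canonical_id))
  gold <- unique(paste(gen$gold$hospital_mentions$message_id,
                       gen$gold$hospital_mentions$canonical_id))
  expect_setequal(pred, gold)
  expect_false(any(mentions$ambiguous))
})
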