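test_that("factor shares are percentages that sum to 100 within each group", {
  x <- tibble::tibble(factor = rep(c("service", "process"), c(50, 50)),
                      polarity = "positive")
  d <- factor_distribution(x)
  expect_equal(sort(d$share), c(50, 50))
  single <- factor_distribution(tibble::tibble(factor = "service",
                                               polarity = "negative"))
  expect_equal(single$share, 100)
  # grouped shares always sum to 100 per group on a generated corpus
  gen <- generate_corpus(generator_config(
    seed = 17, n_threads = 5,
    factor_probs = stats::setNames(rep(0.4, 6),
                                   c("service", "professionalism", "process",
                                     "environment", "impression", "popularity"))))
  inst <- enrich_mentions(gen$gold$instances, gen$messages)
  for (by in list(character(0), "region", "year", c("region", "year"))) {
    tab <- factor_distribution(inst, by = by, include_neutral = TRUE)
    if (length(by)) {
      sums <- tapply(tab$share, tab[, by, drop = FALSE], sum)
      expect_true(all(abs(stats::na.omit(as.vector(sums)) - 100) < 1e-9))
    } else {
      expect_equal(sum(tab$share), 100)
    }
  }
  # filtering then distributing equals distributing the filtered subset
  neg <- factor_distribution(inst, by = "region", polarity = "negative")
  pre <- inst[to_binary(inst$polarity) == "negative", ]
  neg2 <- factor_distribution(pre, by = "region", include_neutral = TRUE)
  expect_equal(neg, neg2)
})

test_that("monthly shares aggregate count-weighted to the yearly table", {
  gen <- generate_corpus(generator_config(
    seed = 23, n_threads = 6,
    factor_probs = stats::setNames(rep(0.5, 6),
                                   c("service", "professionalism", "process",
                                     "environment", "impression", "popularity"))))
  inst <- enrich_mentions(gen$gold$instances, gen$messages)
  yearly <- factor_distribution(inst, by = "year", include_neutral = TRUE)
  monthly <- factor_distribution(inst, by = c("year", "month"),
                                 include_neutral = TRUE)
  agg <- dplyr::summarise(dplyr::group_by(monthly, year, factor), n = sum(n),
                          .groups = "drop_last")
  agg <- dplyr::ungroup(dplyr::mutate(agg, share = 100 * n / sum(n)))
  cmp <- dplyr::left_join(yearly, agg, by = c("year", "factor"))
  expect_equal(cmp$share.x, cmp$share.y)
  expect_equal(cmp$n.x, cmp$n.y)
})

test_that("item shares rank keywords within a factor and ignore input order", {
  x <- tibble::tibble(
    message_id = sprintf("m%d", 1:10),
    factor = "process",
    keyword = rep(c("long term", "right now"), c(7, 3)),
    subcategory = rep(c("f15", "f16"), c(7, 3)),
    polarity = "negative")
  tab <- item_share(x, "process")
  expect_equal(tab$item, c("long term", "right now"))
  expect_equal(tab$share, c(70, 30))
  shuffled <- x[sample(nrow(x)), ]
  expect_equal(item_share(shuffled, "process"), tab)
  expect_equal(item_share(x[x$keyword == "long term", ], "process")$share, 100)
  expect_error(item_share(x, "speed"), class = "hospmine_usage_error")
  expect_equal(item_share(x, "process", level = "subcategory")$item,
               c("f15", "f16"))
})

test_that("co-occurrence counts hospitals inside negative threads with the term", {
  threads <- tibble::tibble(thread_id = c("t1", "t2", "t3"),
                            title = "title",
                            region = "Daegu",
                            message_ids = list("m1", "m2", "m3"))
  messages <- tibble::tibble(
    message_id = c("m1", "m2", "m3"),
    thread_id = c("t1", "t2", "t3"),
    region = "Daegu", posted_at = "2009-01-01",
    raw_text = c("emergency at palgong child was terrible.",
                 "emergency but all good at palgong child.",
                 "quiet day no term here."))
  sen <- mini_sentiment()
  labels <- classify_messages(messages, sen)
  mentions <- tibble::tibble(message_id = c("m1", "m2"),
                             canonical_id = c("H04", "H04"))
  tab <- cooccurrence(threads, messages, mentions, labels, "emergency")
  # only t1 is negatively opinionated and contains the term
  expect_equal(attr(tab, "n_denominator"), 1L)
  expect_equal(tab$canonical_id, "H04")
  expect_equal(tab$share, 100)
  # absent term -> empty table
  expect_equal(nrow(cooccurrence(threads, messages, mentions, labels,
                                 "ambulance")), 0L)
})

test_that("recommendation share is positive instances over all classified", {
  x <- tibble::tibble(factor = "service",
                      polarity = rep(c("positive", "neutral", "negative"),
                                     c(1, 1, 1)))
  expect_equal(recommendation_share(x), round_half_up(100 / 3, 2))
  expect_equal(recommendation_share(tibble::tibble(polarity = rep("negative", 5),
                                                   factor = "x")), 0)
  expect_equal(recommendation_share(tibble::tibble(polarity = rep("positive", 5),
                                                   factor = "x")), 100)
})
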