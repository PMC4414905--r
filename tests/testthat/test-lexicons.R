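write_hosp_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c("canonical_id\tcanonical_name\tregion\taliases", lines), path)
  path
}

test_that("hospital lexicon parses, dedupes aliases and enforces invariants", {
  p <- write_hosp_tsv("H1\tSunshine Pediatric\tSeoul\tSP Clinic")
  lex <- load_hospital_lexicon(p)
  expect_equal(nrow(lex), 1L)
  expect_setequal(lex$aliases[[1]], c("Sunshine Pediatric", "SP Clinic"))

  dup <- write_hosp_tsv(c("H1\tA Clinic\tSeoul\ta",
                          "H1\tB Clinic\tBusan\tb"))
  expect_error(load_hospital_lexicon(dup), "H1", class = "hospmine_validation_error")

  bad <- write_hosp_tsv("H1\tA Clinic\tSeoul\ta||b")
  expect_error(load_hospital_lexicon(bad), "row 1", class = "hospmine_validation_error")

  expect_error(load_hospital_lexicon(tempfile()), class = "hospmine_io_error")

  multi <- write_hosp_tsv(c("H1\tA Clinic\tSeoul\ta",
                            "H2\tB Clinic\tSeoul\tb",
                            "H3\tC Clinic\tBusan\tc"))
  lex3 <- load_hospital_lexicon(multi)
  expect_equal(nrow(lex3), 3L)
  expect_setequal(lex3$canonical_id[lex3$region == "Seoul"], c("H1", "H2"))
})

test_that("lexicons round-trip through their TSV representation", {
  hosp <- mini_hospitals()
  p1 <- withr::local_tempfile(fileext = ".tsv")
  write_hospital_lexicon(hosp, p1)
  expect_equal(load_hospital_lexicon(p1), hosp)

  fac <- mini_factors()
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_factor_lexicon(fac, p2)
  expect_equal(load_factor_lexicon(p2), fac)

  sen <- mini_sentiment()
  p3 <- withr::local_tempfile(fileext = ".tsv")
  write_sentiment_lexicon(sen, p3)
  expect_equal(load_sentiment_lexicon(p3), sen)
})

test_that("factor lexicon enforces the f-code/e-code pairing rule", {
  ok <- tibble::tibble(keyword = "waiting time", factor = "process",
                       subcategory = "f15", equivalents = list(character(0)))
  lex <- validate_factor_lexicon(ok)
  expect_equal(lex$factor, "process")

  bad_e <- tibble::tibble(keyword = "parking", factor = "environment",
                          subcategory = "e9", equivalents = list(character(0)))
  expect_error(validate_factor_lexicon(bad_e), "e9",
               class = "hospmine_validation_error")

  bad_f <- tibble::tibble(keyword = "famous", factor = "popularity",
                          subcategory = "f3", equivalents = list(character(0)))
  expect_error(validate_factor_lexicon(bad_f), class = "hospmine_validation_error")

  unknown <- tibble::tibble(keyword = "x", factor = "speed",
                            subcategory = "f1", equivalents = list(character(0)))
  expect_error(validate_factor_lexicon(unknown), "speed",
               class = "hospmine_validation_error")

  # every shipped entry satisfies the rule (full scan)
  shipped <- example_lexicons()$factors
  is_e <- startsWith(shipped$subcategory, "e")
  expect_true(all(is_e == (shipped$factor %in% c("impression", "popularity"))))
})

test_that("equivalents become lookup keys resolving to the owning entry", {
  fac <- mini_factors()
  hit_q <- lookup_keyword(fac, "queue")
  hit_w <- lookup_keyword(fac, "  WAIT ")
  expect_equal(hit_q$keyword, "waiting time")
  expect_equal(hit_w$keyword, "waiting time")
  expect_equal(hit_q$entry, hit_w$entry)
  # lookup equals a linear scan over the expanded key table
  tbl <- factor_lookup_table(fac)
  for (q in c("queue", "waiting", "parking", "nonexistent")) {
    expect_equal(lookup_keyword(fac, q), tbl[tbl$key == normalize_string(q), ])
  }
})

test_that("cross-lexicon collisions are reported as warnings, not errors", {
  expect_equal(nrow(validate_lexicons(mini_hospitals(), mini_factors(),
                                      mini_sentiment())), 0L)
  hosp <- validate_hospital_lexicon(tibble::tibble(
    canonical_id = "H1", canonical_name = "Popular Clinic", region = "Seoul",
    aliases = list(c("popular clinic", "parking"))))
  sen <- sentiment_lexicon(positive = c("good", "popular clinic"),
                           negative = "bad")
  report <- validate_lexicons(hosp, mini_factors(), sen)
  expect_equal(nrow(report), 2L)
  expect_setequal(report$value, c("popular clinic", "parking"))
})
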