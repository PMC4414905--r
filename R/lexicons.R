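# Lexicon loaders and validators.
#
# Three dictionaries drive the pipeline: hospital names (canonical name +
# noisy aliases + region), quality-factor keywords (six factors with
# subcategory codes f1-f29 / e1-e10), and sentiment cues. All files are UTF-8
# TSV with a header row; alias/equivalent lists are pipe-delimited within a
# cell. Matching everywhere happens on normalize_string() output, applied
# identically at load and query time.

read_tsv_strict <- function(path) {
  if (!file.exists(path)) {
    hm_abort(sprintf("lexicon file not found: %s", path), class = "hospmine_io_error")
  }
  df <- utils::read.delim(path, sep = "\t", quote = "", colClasses = "character",
                          check.names = FALSE, na.strings = NULL,
                          fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  as_tibble(df)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    hm_abort(sprintf("%s: missing required column(s): %s",
                     path, paste(missing, collapse = ", ")),
             class = "hospmine_validation_error")
  }
}

split_pipe <- function(x) {
  if (!nzchar(x)) character(0) else strsplit(x, "|", fixed = TRUE)[[1]]
}

#' Load a hospital name lexicon
#'
#' Reads a TSV with columns `canonical_id`, `canonical_name`, `region`, and
#' `aliases` (pipe-delimited surface forms: acronyms, abbreviations, common
#' misspellings). The canonical name itself is always added to the alias set,
#' and alias sets are deduplicated.
#'
#' @param path path to the TSV file.
#' @return a tibble of class `hospital_lexicon` with columns `canonical_id`,
#'   `canonical_name`, `region`, and list-column `aliases`.
#' @export
load_hospital_lexicon <- function(path) {
  df <- read_tsv_strict(path)
  require_columns(df, c("canonical_id", "canonical_name", "region", "aliases"), path)
  alias_sets <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    parts <- split_pipe(df$aliases[i])
    if (any(!nzchar(trimws(parts)))) {
      hm_abort(sprintf("%s: empty alias in row %d", path, i),
               class = "hospmine_validation_error")
    }
    alias_sets[[i]] <- unique(c(df$canonical_name[i], parts))
  }
  lex <- tibble(canonical_id = df$canonical_id,
                canonical_name = df$canonical_name,
                region = df$region,
                aliases = alias_sets)
  validate_hospital_lexicon(lex, source = path)
}

#' Construct/validate a hospital lexicon from a tibble
#'
#' @param lex tibble with columns `canonical_id`, `canonical_name`, `region`,
#'   and list-column `aliases`.
#' @param source label used in error messages.
#' @return the validated `hospital_lexicon` tibble.
#' @export
validate_hospital_lexicon <- function(lex, source = "hospital lexicon") {
  dup <- lex$canonical_id[duplicated(lex$canonical_id)]
  if (length(dup)) {
    hm_abort(sprintf("%s: duplicate canonical_id: %s", source,
                     paste(unique(dup), collapse = ", ")),
             class = "hospmine_validation_error")
  }
  if (any(!nzchar(trimws(lex$canonical_name)))) {
    hm_abort(sprintf("%s: canonical_name must be nonempty", source),
             class = "hospmine_validation_error")
  }
  if (any(!nzchar(trimws(lex$region)))) {
    hm_abort(sprintf("%s: region must be nonempty", source),
             class = "hospmine_validation_error")
  }
  lex$aliases <- lapply(seq_len(nrow(lex)), function(i) {
    unique(c(lex$canonical_name[i], lex$aliases[[i]]))
  })
  class(lex) <- c("hospital_lexicon", class(tibble()))
  lex
}

#' Write a hospital lexicon back to TSV
#'
#' Inverse of [load_hospital_lexicon()]: loading the written file yields an
#' identical entry collection.
#'
#' @param lex a `hospital_lexicon` tibble.
#' @param path output path.
#' @export
write_hospital_lexicon <- function(lex, path) {
  df <- data.frame(canonical_id = lex$canonical_id,
                   canonical_name = lex$canonical_name,
                   region = lex$region,
                   aliases = vapply(lex$aliases, paste, "", collapse = "|"),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

valid_subcategory <- function(code) {
  grepl("^f([1-9]|1[0-9]|2[0-9])$", code) | grepl("^e([1-9]|10)$", code)
}

#' Load a quality-factor keyword lexicon
#'
#' Reads a TSV with columns `keyword`, `factor`, `subcategory`, `equivalents`
#' (pipe-delimited surface forms treated as additional lookup keys for the
#' same entry). The factor must be one of the six quality factors; functional
#' subcategory codes f1-f29 may only be attached to service, professionalism,
#' process or environment, and emotional codes e1-e10 only to impression or
#' popularity.
#'
#' @param path path to the TSV file.
#' @return a tibble of class `factor_lexicon` with columns `keyword`,
#'   `factor`, `subcategory`, and list-column `equivalents`.
#' @export
load_factor_lexicon <- function(path) {
  df <- read_tsv_strict(path)
  require_columns(df, c("keyword", "factor", "subcategory", "equivalents"), path)
  lex <- tibble(keyword = df$keyword,
                factor = df$factor,
                subcategory = df$subcategory,
                equivalents = lapply(df$equivalents, split_pipe))
  validate_factor_lexicon(lex, source = path)
}

#' Construct/validate a factor lexicon from a tibble
#'
#' @param lex tibble with columns `keyword`, `factor`, `subcategory`, and
#'   list-column `equivalents`.
#' @param source label used in error messages.
#' @return the validated `factor_lexicon` tibble.
#' @export
validate_factor_lexicon <- function(lex, source = "factor lexicon") {
  if (any(!nzchar(trimws(lex$keyword)))) {
    hm_abort(sprintf("%s: keyword must be nonempty", source),
             class = "hospmine_validation_error")
  }
  bad_factor <- setdiff(unique(lex$factor), FACTOR_NAMES)
  if (length(bad_factor)) {
    hm_abort(sprintf("%s: unknown factor name(s): %s", source,
                     paste(bad_factor, collapse = ", ")),
             class = "hospmine_validation_error")
  }
  bad_code <- !valid_subcategory(lex$subcategory)
  if (any(bad_code)) {
    hm_abort(sprintf("%s: invalid subcategory code(s): %s", source,
                     paste(unique(lex$subcategory[bad_code]), collapse = ", ")),
             class = "hospmine_validation_error")
  }
  is_e <- startsWith(lex$subcategory, "e")
  functional <- lex$factor %in% FUNCTIONAL_FACTORS
  mismatch <- (is_e & functional) | (!is_e & !functional)
  if (any(mismatch)) {
    i <- which(mismatch)[1]
    hm_abort(sprintf(
      "%s: subcategory %s cannot be paired with factor '%s' (f-codes belong to %s; e-codes to impression/popularity)",
      source, lex$subcategory[i], lex$factor[i],
      paste(FUNCTIONAL_FACTORS, collapse = "/")),
      class = "hospmine_validation_error")
  }
  key <- paste(lex$keyword, lex$factor, lex$subcategory, sep = "\r")
  if (anyDuplicated(key)) {
    hm_abort(sprintf("%s: duplicate (keyword, factor, subcategory) entries", source),
             class = "hospmine_validation_error")
  }
  class(lex) <- c("factor_lexicon", class(tibble()))
  lex
}

#' Write a factor lexicon back to TSV
#' @param lex a `factor_lexicon` tibble.
#' @param path output path.
#' @export
write_factor_lexicon <- function(lex, path) {
  df <- data.frame(keyword = lex$keyword,
                   factor = lex$factor,
                   subcategory = lex$subcategory,
                   equivalents = vapply(lex$equivalents, paste, "", collapse = "|"),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Expand a factor lexicon into a normalized lookup table
#'
#' Each keyword and each of its equivalents becomes a lookup key pointing at
#' the owning entry. Keys are normalized; `n_tokens` caches the token count of
#' each key for the n-gram matcher.
#'
#' @param factors a `factor_lexicon` tibble.
#' @return tibble with columns `key`, `entry`, `keyword`, `factor`,
#'   `subcategory`, `n_tokens`.
#' @export
factor_lookup_table <- function(factors) {
  keys <- lapply(seq_len(nrow(factors)), function(i) {
    unique(normalize_string(c(factors$keyword[i], factors$equivalents[[i]])))
  })
  lens <- lengths(keys)
  out <- tibble(key = unlist(keys),
                entry = rep(seq_len(nrow(factors)), lens),
                keyword = rep(factors$keyword, lens),
                factor = rep(factors$factor, lens),
                subcategory = rep(factors$subcategory, lens))
  out$n_tokens <- stri_count_regex(out$key, "[\\p{L}\\p{N}]+")
  out
}

#' Look up factor lexicon entries by keyword or equivalent
#'
#' @param factors a `factor_lexicon` tibble.
#' @param query character vector of surface forms (normalized internally).
#' @return tibble of matching lookup rows (possibly zero rows).
#' @export
lookup_keyword <- function(factors, query) {
  tbl <- factor_lookup_table(factors)
  tbl[tbl$key %in% normalize_string(query), , drop = FALSE]
}

#' Load a sentiment cue lexicon
#'
#' Reads a TSV with columns `cue` and `role`, where role is one of
#' `positive`, `negative`, or `negation`. Positive and negative cue sets must
#' be nonempty and disjoint; negation markers are optional (default empty).
#'
#' @param path path to the TSV file.
#' @return an object of class `sentiment_lexicon`: a list with character
#'   vectors `positive`, `negative`, `negation`.
#' @export
load_sentiment_lexicon <- function(path) {
  df <- read_tsv_strict(path)
  require_columns(df, c("cue", "role"), path)
  bad <- setdiff(unique(df$role), c("positive", "negative", "negation"))
  if (length(bad)) {
    hm_abort(sprintf("%s: unknown role(s): %s", path, paste(bad, collapse = ", ")),
             class = "hospmine_validation_error")
  }
  sentiment_lexicon(positive = df$cue[df$role == "positive"],
                    negative = df$cue[df$role == "negative"],
                    negation = df$cue[df$role == "negation"])
}

#' Construct a sentiment lexicon
#'
#' @param positive,negative character vectors of cue surface forms signalling
#'   recommendation / non-recommendation.
#' @param negation optional character vector of negation markers (single
#'   tokens); a cue within the negation window after a marker flips sign.
#' @return an object of class `sentiment_lexicon`.
#' @export
sentiment_lexicon <- function(positive, negative, negation = character(0)) {
  positive <- unique(positive[nzchar(positive)])
  negative <- unique(negative[nzchar(negative)])
  negation <- unique(negation[nzchar(negation)])
  if (!length(positive) || !length(negative)) {
    hm_abort("sentiment lexicon needs nonempty positive and negative cue sets",
             class = "hospmine_validation_error")
  }
  overlap <- intersect(normalize_string(positive), normalize_string(negative))
  if (length(overlap)) {
    hm_abort(sprintf("sentiment lexicon: cue(s) listed as both positive and negative: %s",
                     paste(overlap, collapse = ", ")),
             class = "hospmine_validation_error")
  }
  structure(list(positive = positive, negative = negative, negation = negation),
            class = "sentiment_lexicon")
}

#' Write a sentiment lexicon back to TSV
#' @param lex a `sentiment_lexicon`.
#' @param path output path.
#' @export
write_sentiment_lexicon <- function(lex, path) {
  df <- data.frame(cue = c(lex$positive, lex$negative, lex$negation),
                   role = c(rep("positive", length(lex$positive)),
                            rep("negative", length(lex$negative)),
                            rep("negation", length(lex$negation))),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Cross-lexicon collision report
#'
#' Reports, as warnings rather than errors, surface forms that appear in more
#' than one lexicon after normalization (a hospital alias identical to a
#' factor keyword or sentiment cue, or a factor key identical to a cue). Such
#' collisions make extraction output ambiguous to interpret downstream.
#'
#' @param hospitals a `hospital_lexicon`.
#' @param factors a `factor_lexicon`.
#' @param sentiment a `sentiment_lexicon`.
#' @return tibble with columns `kind` (which pair of lexicons collide) and
#'   `value` (the normalized colliding surface form); zero rows when disjoint.
#' @export
validate_lexicons <- function(hospitals, factors, sentiment) {
  aliases <- unique(normalize_string(unlist(hospitals$aliases)))
  fkeys <- unique(factor_lookup_table(factors)$key)
  cues <- unique(normalize_string(c(sentiment$positive, sentiment$negative)))
  pairs <- list(
    list(kind = "hospital_alias/factor_keyword", value = intersect(aliases, fkeys)),
    list(kind = "hospital_alias/sentiment_cue", value = intersect(aliases, cues)),
    list(kind = "factor_keyword/sentiment_cue", value = intersect(fkeys, cues))
  )
  out <- bind_rows(lapply(pairs, function(p) {
    if (!length(p$value)) NULL else tibble(kind = p$kind, value = p$value)
  }))
  if (is.null(out) || nrow(out) == 0L) {
    out <- tibble(kind = character(), value = character())
  }
  out
}

#' Example stand-in lexicons shipped with the package
#'
#' Loads the small synthetic English lexicons under `inst/extdata` (hospital
#' roster, factor keywords, sentiment cues). These are stand-ins sized at tens
#' of keywords per factor, intended for tests, examples and synthetic corpus
#' generation; real deployments supply their own TSV files.
#'
#' @return list with elements `hospitals`, `factors`, `sentiment`.
#' @export
example_lexicons <- function() {
  dir <- system.file("extdata", package = "hospmine")
  list(hospitals = load_hospital_lexicon(file.path(dir, "hospitals.tsv")),
       factors = load_factor_lexicon(file.path(dir, "factors.tsv")),
       sentiment = load_sentiment_lexicon(file.path(dir, "sentiment.tsv")))
}
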