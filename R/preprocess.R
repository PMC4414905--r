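#' @importFrom stringi stri_trans_tolower stri_detect_regex stri_locate_all_regex
#'   stri_sub stri_length stri_replace_all_regex stri_trim_both stri_count_regex
NULL

#' Normalize text with an offset map back to the raw string
#'
#' Lowercases the text and collapses every run of whitespace (including
#' newlines and tabs) to a single space, trimming leading and trailing
#' whitespace. Community messages are rife with misspellings and erratic
#' spacing, so all dictionary matching in this package operates on this
#' normalized form; the returned offset map projects spans found in the
#' normalized text back onto the raw input.
#'
#' @param text a single character string.
#' @return an object of class `hm_normalized`: a list with elements
#'   `text` (the normalized string), `raw` (the input), and integer vectors
#'   `map_start`/`map_end` giving, for each character of the normalized text,
#'   the 0-based half-open raw-text span it came from.
#' @seealso [project_span()], [normalize_string()]
#' @export
#' @examples
#' n <- normalize_text("  Good   DOCTOR ")
#' n$text                    # "good doctor"
#' project_span(n, 5, 11)    # raw span covering "DOCTOR"
normalize_text <- function(text) {
  stopifnot(length(text) == 1L)
  text <- if (is.na(text)) "" else as.character(text)
  raw <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(raw)
  out <- character(n)
  ms <- integer(n)
  me <- integer(n)
  k <- 0L
  if (n > 0L) {
    is_ws <- stri_detect_regex(raw, "^\\s$")
    pending <- NA_integer_
    started <- FALSE
    for (i in seq_len(n)) {
      if (is_ws[i]) {
        if (started && is.na(pending)) pending <- i
      } else {
        if (!is.na(pending)) {
          k <- k + 1L
          out[k] <- " "
          ms[k] <- pending - 1L
          me[k] <- pending
          pending <- NA_integer_
        }
        k <- k + 1L
        out[k] <- raw[i]
        ms[k] <- i - 1L
        me[k] <- i
        started <- TRUE
      }
    }
  }
  collapsed <- paste(out[seq_len(k)], collapse = "")
  lowered <- stri_trans_tolower(collapsed)
  if (stri_length(lowered) == k) {
    norm <- lowered
    ms <- ms[seq_len(k)]
    me <- me[seq_len(k)]
  } else {
    # Rare case: case mapping changed the string length; lower per character
    # so the offset map stays total (each output char maps to its source char).
    ch <- stri_trans_tolower(out[seq_len(k)])
    lens <- stri_length(ch)
    norm <- paste(ch, collapse = "")
    ms <- rep(ms[seq_len(k)], lens)
    me <- rep(me[seq_len(k)], lens)
  }
  structure(list(text = norm, raw = text, map_start = ms, map_end = me),
            class = "hm_normalized")
}

#' @export
print.hm_normalized <- function(x, ...) {
  cat("<hm_normalized> ", encodeString(x$text, quote = '"'), "\n", sep = "")
  invisible(x)
}

#' Project a normalized-text span back to the raw text
#'
#' @param normalized an `hm_normalized` object from [normalize_text()].
#' @param start,end 0-based half-open span in the normalized text.
#' @return named integer vector `c(start, end)`: the 0-based half-open raw span.
#' @export
project_span <- function(normalized, start, end) {
  stopifnot(inherits(normalized, "hm_normalized"))
  len <- stri_length(normalized$text)
  if (start < 0 || end > len || start >= end) {
    hm_abort(sprintf("span [%d, %d) out of bounds for normalized text of length %d",
                     start, end, len))
  }
  c(start = normalized$map_start[start + 1L], end = normalized$map_end[end])
}

#' Vectorized text normalization
#'
#' The string-only fast path of [normalize_text()]: lowercase, collapse
#' whitespace runs to single spaces, trim. Applied identically at lexicon load
#' time and at query time so that dictionary matching is insensitive to case
#' and spacing noise.
#'
#' @param x character vector.
#' @return character vector of normalized strings.
#' @export
normalize_string <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  stri_trans_tolower(stri_trim_both(stri_replace_all_regex(x, "\\s+", " ")))
}

#' Split text into sentences
#'
#' Sentences are delimited by `.`, `!`, `?` or a newline; the punctuation
#' delimiters stay attached to the preceding sentence, surrounding whitespace
#' (including the newline delimiter itself) is stripped, and segments that
#' contain only delimiters are dropped. No abbreviation handling is attempted:
#' community messages are short and the corpus language model is a pluggable
#' normalizer away from anything more elaborate.
#'
#' @param text a single character string.
#' @return a tibble with columns `sentence`, `start`, `end` (0-based half-open
#'   spans in `text`), in document order.
#' @export
#' @examples
#' split_sentences("Nice staff. Long wait!")
split_sentences <- function(text) {
  empty <- tibble(sentence = character(), start = integer(), end = integer())
  if (length(text) != 1L || is.na(text) || !nzchar(text)) return(empty)
  loc <- stri_locate_all_regex(text, "[^.!?\n]*[.!?\n]+|[^.!?\n]+")[[1]]
  if (nrow(loc) == 0L || is.na(loc[1, 1])) return(empty)
  segs <- stri_sub(text, loc[, 1], loc[, 2])
  res <- vector("list", nrow(loc))
  for (i in seq_len(nrow(loc))) {
    seg <- segs[i]
    lead <- attr(regexpr("^\\s*", seg, perl = TRUE), "match.length")
    trail <- attr(regexpr("\\s*$", seg, perl = TRUE), "match.length")
    s <- loc[i, 1] + lead
    e <- loc[i, 2] - trail
    if (s > e) next
    sent <- stri_sub(text, s, e)
    if (stri_detect_regex(sent, "^[.!?\\s]*$")) next
    res[[i]] <- tibble(sentence = unname(sent),
                       start = as.integer(s - 1L), end = as.integer(e))
  }
  out <- bind_rows(res)
  if (nrow(out) == 0L) empty else out
}

#' Tokenize text into word tokens with offsets
#'
#' Tokens are maximal runs of Unicode letters and digits; offsets are 0-based
#' and half-open.
#'
#' @param text a single character string.
#' @return a tibble with columns `token`, `start`, `end`.
#' @export
#' @examples
#' tokenize("a-b c")
tokenize <- function(text) {
  empty <- tibble(token = character(), start = integer(), end = integer())
  if (length(text) != 1L || is.na(text) || !nzchar(text)) return(empty)
  loc <- stri_locate_all_regex(text, "[\\p{L}\\p{N}]+")[[1]]
  if (nrow(loc) == 0L || is.na(loc[1, 1])) return(empty)
  tibble(token = stri_sub(text, loc[, 1], loc[, 2]),
         start = as.integer(loc[, 1] - 1L),
         end = as.integer(loc[, 2]))
}
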