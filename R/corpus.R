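# Corpus representation and I/O.
#
# The content structure has three levels: threads -> messages -> sentences.
# On disk a corpus is line-delimited JSON, one self-describing record per
# line discriminated by a "kind" field ("thread" or "message"); streamable
# and appendable. Dates are ISO-8601 strings; analytics bins by year and
# year-month.

#' Strip HTML markup, keeping visible text only
#'
#' Removes script and style element contents entirely (JavaScript, CSS,
#' ad markup), decodes entity references, and turns block-level element
#' boundaries into newlines. Best-effort on malformed markup via the
#' lenient libxml2 HTML parser.
#'
#' @param html a single character string containing an HTML document or
#'   fragment (well-formedness not required).
#' @return the visible plain text.
#' @export
#' @examples
#' strip_html("<p>good doctor</p>")
#' strip_html("<script>x=1</script>hi")
strip_html <- function(html) {
  if (length(html) != 1L || is.na(html) || !nzchar(trimws(html))) return("")
  tidy_lines <- function(txt) {
    lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
    lines <- stri_replace_all_regex(lines, "^\\s+|\\s+$", "")
    paste(lines[nzchar(lines)], collapse = "\n")
  }
  # markup-free input is already plain text
  if (!grepl("<", html, fixed = TRUE)) return(tidy_lines(html))
  doc <- xml2::read_html(html)
  blocks <- c("p", "div", "li", "ul", "ol", "table", "tr", "td", "th",
              "h1", "h2", "h3", "h4", "h5", "h6", "blockquote", "pre",
              "section", "article", "header", "footer", "form", "hr",
              "body", "html")
  rec <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "text") return(xml2::xml_text(node))
    if (nm %in% c("script", "style", "comment")) return("")
    if (nm == "br") return("\n")
    kids <- xml2::xml_contents(node)
    inner <- paste0(vapply(kids, rec, character(1)), collapse = "")
    if (nm %in% blocks) paste0("\n", inner, "\n") else inner
  }
  tidy_lines(rec(xml2::xml_root(doc)))
}

#' Read a line-delimited corpus file
#'
#' Each nonempty line must be a JSON object with a `kind` field: threads carry
#' `thread_id`, `title`, `region`, `message_ids`; messages carry `message_id`,
#' `thread_id`, `region`, `posted_at`, `raw_text`. Referential integrity is
#' validated in both directions (every listed message id resolves; every
#' message's thread exists).
#'
#' @param path path to a `.jsonl` corpus file.
#' @return list with tibbles `threads` (`thread_id`, `title`, `region`,
#'   list-column `message_ids`) and `messages` (`message_id`, `thread_id`,
#'   `region`, `posted_at`, `raw_text`), orders preserved from the file.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) {
    hm_abort(sprintf("corpus file not found: %s", path), class = "hospmine_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  threads <- list()
  messages <- list()
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[i]))) next
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) {
                      hm_abort(sprintf("%s: malformed record at line %d: %s",
                                       path, i, conditionMessage(e)),
                               class = "hospmine_io_error")
                    })
    kind <- rec$kind %||% ""
    if (identical(kind, "thread")) {
      threads[[length(threads) + 1L]] <- tibble(
        thread_id = as.character(rec$thread_id),
        title = as.character(rec$title %||% ""),
        region = as.character(rec$region %||% ""),
        message_ids = list(as.character(rec$message_ids %||% character(0))))
    } else if (identical(kind, "message")) {
      messages[[length(messages) + 1L]] <- tibble(
        message_id = as.character(rec$message_id),
        thread_id = as.character(rec$thread_id),
        region = as.character(rec$region %||% ""),
        posted_at = as.character(rec$posted_at %||% ""),
        raw_text = as.character(rec$raw_text %||% ""))
    } else {
      hm_abort(sprintf("%s: unknown record kind at line %d", path, i),
               class = "hospmine_io_error")
    }
  }
  threads <- if (length(threads)) bind_rows(threads) else
    tibble(thread_id = character(), title = character(), region = character(),
           message_ids = list())
  messages <- if (length(messages)) bind_rows(messages) else
    tibble(message_id = character(), thread_id = character(), region = character(),
           posted_at = character(), raw_text = character())
  validate_corpus(threads, messages)
  list(threads = threads, messages = messages)
}

validate_corpus <- function(threads, messages) {
  if (anyDuplicated(messages$message_id)) {
    hm_abort("duplicate message_id in corpus", class = "hospmine_validation_error")
  }
  if (anyDuplicated(threads$thread_id)) {
    hm_abort("duplicate thread_id in corpus", class = "hospmine_validation_error")
  }
  listed <- unlist(threads$message_ids)
  dangling <- setdiff(listed, messages$message_id)
  if (length(dangling)) {
    hm_abort(sprintf("thread message list references unknown message(s): %s",
                     paste(utils::head(dangling, 5), collapse = ", ")),
             class = "hospmine_validation_error")
  }
  orphan <- setdiff(messages$thread_id, threads$thread_id)
  if (length(orphan)) {
    hm_abort(sprintf("message(s) reference unknown thread(s): %s",
                     paste(utils::head(orphan, 5), collapse = ", ")),
             class = "hospmine_validation_error")
  }
  invisible(TRUE)
}

#' Write a corpus to a line-delimited JSON file
#'
#' Threads are written first, then messages, both in tibble order with fixed
#' field order, so re-writing a just-read corpus is byte-identical.
#'
#' @param threads,messages corpus tibbles as returned by [read_corpus()].
#' @param path output path.
#' @export
write_corpus <- function(threads, messages, path) {
  validate_corpus(threads, messages)
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(threads))) {
    rec <- list(kind = "thread",
                thread_id = threads$thread_id[i],
                title = threads$title[i],
                region = threads$region[i],
                message_ids = as.list(threads$message_ids[[i]]))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con, useBytes = TRUE)
  }
  for (i in seq_len(nrow(messages))) {
    rec <- list(kind = "message",
                message_id = messages$message_id[i],
                thread_id = messages$thread_id[i],
                region = messages$region[i],
                posted_at = messages$posted_at[i],
                raw_text = messages$raw_text[i])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con, useBytes = TRUE)
  }
  invisible(path)
}

#' Corpus summary statistics by region
#'
#' Computes, per region, the thread count, message count, messages-per-thread
#' ratio, and (when `factor_message_ids` is supplied) the number and
#' percentage of messages containing at least one detected quality-factor
#' keyword. A `Total` row sums the counts (its percentage is computed from
#' the totals), and an `Average` row holds the macro mean of the per-region
#' ratios — each region weighted equally.
#'
#' @param threads,messages corpus tibbles.
#' @param factor_message_ids optional character vector of message ids that
#'   contain at least one factor mention.
#' @return tibble with columns `region`, `n_threads`, `n_messages`,
#'   `messages_per_thread`, `n_factor_messages`, `factor_pct`.
#' @export
corpus_stats <- function(threads, messages, factor_message_ids = NULL) {
  regs <- sort(unique(threads$region))
  rows <- lapply(regs, function(r) {
    nt <- sum(threads$region == r)
    nm <- sum(messages$region == r)
    nf <- if (is.null(factor_message_ids)) NA_integer_ else
      sum(messages$region == r & messages$message_id %in% factor_message_ids)
    tibble(region = r, n_threads = nt, n_messages = nm,
           messages_per_thread = if (nt > 0) nm / nt else NA_real_,
           n_factor_messages = nf,
           factor_pct = if (is.null(factor_message_ids) || nm == 0) NA_real_
                        else 100 * nf / nm)
  })
  per <- bind_rows(rows)
  total <- tibble(region = "Total",
                  n_threads = sum(per$n_threads),
                  n_messages = sum(per$n_messages),
                  messages_per_thread = NA_real_,
                  n_factor_messages = if (is.null(factor_message_ids)) NA_integer_
                                      else sum(per$n_factor_messages),
                  factor_pct = if (is.null(factor_message_ids) || sum(per$n_messages) == 0)
                    NA_real_ else 100 * sum(per$n_factor_messages) / sum(per$n_messages))
  avg <- tibble(region = "Average",
                n_threads = NA_integer_, n_messages = NA_integer_,
                messages_per_thread = mean(per$messages_per_thread),
                n_factor_messages = NA_integer_, factor_pct = NA_real_)
  bind_rows(per, total, avg)
}
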