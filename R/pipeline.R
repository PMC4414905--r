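# End-to-end orchestration of the detection/classification stages:
# (HTML stripping) -> preprocessing -> hospital name extraction -> message
# filtering -> quality factor detection -> mood-flow classification ->
# factor polarity assignment, with a machine-readable run manifest.

#' Pipeline configuration
#'
#' Lexicons and corpus may be given as file paths (TSV / JSONL) or as
#' already-loaded objects; paths are resolved at run start.
#'
#' @param hospitals,factors,sentiment lexicon paths or loaded lexicons.
#' @param corpus corpus `.jsonl` path or a `list(threads, messages)`.
#' @param strip_html run [strip_html()] over raw message text first.
#' @param include_titles concatenate each thread's title ahead of its first
#'   message's text for detection (default off; titles are otherwise unused).
#' @param max_rel_distance,max_ngram hospital matcher settings
#'   (see [extract_hospital_mentions()]).
#' @param sentiment_mode `"presence"` or `"last"` (see [mood_flow_classify()]).
#' @param negation_window see [sentence_polarity()].
#' @param include_neutral analytics denominator switch (see
#'   [factor_distribution()]); recorded here so a run is self-describing.
#' @param output_dir optional directory; when set, every intermediate
#'   artifact and the manifest are written there as TSV/JSON.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(hospitals, factors, sentiment, corpus,
                            strip_html = FALSE, include_titles = FALSE,
                            max_rel_distance = 0.25, max_ngram = 5,
                            sentiment_mode = "presence", negation_window = 2,
                            include_neutral = FALSE, output_dir = NULL) {
  structure(list(hospitals = hospitals, factors = factors,
                 sentiment = sentiment, corpus = corpus,
                 strip_html = strip_html, include_titles = include_titles,
                 max_rel_distance = max_rel_distance, max_ngram = max_ngram,
                 sentiment_mode = sentiment_mode,
                 negation_window = negation_window,
                 include_neutral = include_neutral, output_dir = output_dir),
            class = "pipeline_config")
}

resolve_input <- function(x, loader) {
  if (is.character(x) && length(x) == 1L) loader(x) else x
}

config_hash <- function(config) {
  desc <- list(
    hospitals = if (is.character(config$hospitals)) config$hospitals else "<object>",
    factors = if (is.character(config$factors)) config$factors else "<object>",
    sentiment = if (is.character(config$sentiment)) config$sentiment else "<object>",
    corpus = if (is.character(config$corpus)) config$corpus else "<object>",
    strip_html = config$strip_html, include_titles = config$include_titles,
    max_rel_distance = config$max_rel_distance, max_ngram = config$max_ngram,
    sentiment_mode = config$sentiment_mode,
    negation_window = config$negation_window,
    include_neutral = config$include_neutral)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(desc, auto_unbox = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

write_tsv_artifact <- function(df, path) {
  df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

#' Run the full detection and classification pipeline
#'
#' Executes the stages in order and returns every intermediate artifact plus
#' a manifest with the configuration hash and the count at each stage
#' (messages in, retained after filtering, hospital and factor mentions,
#' per-class label counts, polarized instances). Stage counts are monotone:
#' retained messages never exceed input messages, classified instances never
#' exceed detected factor mentions.
#'
#' @param config a [pipeline_config()].
#' @return list with `mentions`, `retained`, `factor_mentions`, `labels`,
#'   `instances` (enriched with region/year/month), and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  hospitals <- resolve_input(config$hospitals, load_hospital_lexicon)
  factors <- resolve_input(config$factors, load_factor_lexicon)
  sentiment <- resolve_input(config$sentiment, load_sentiment_lexicon)
  corpus <- resolve_input(config$corpus, read_corpus)
  threads <- corpus$threads
  messages <- corpus$messages
  if (config$strip_html && nrow(messages)) {
    messages$raw_text <- vapply(messages$raw_text, strip_html, character(1),
                                USE.NAMES = FALSE)
  }
  if (config$include_titles && nrow(messages)) {
    first_ids <- vapply(threads$message_ids,
                        function(ids) if (length(ids)) ids[1] else NA_character_,
                        character(1))
    idx <- match(messages$message_id, first_ids)
    hit <- !is.na(idx)
    messages$raw_text[hit] <- paste0(threads$title[idx[hit]], ". ",
                                     messages$raw_text[hit])
  }
  mentions <- extract_corpus_mentions(messages, hospitals,
                                      max_rel_distance = config$max_rel_distance,
                                      max_ngram = config$max_ngram)
  retained <- filter_messages(messages, mentions)
  factor_mentions <- detect_corpus_factors(retained, factors)
  labels <- classify_messages(retained, sentiment,
                              mode = config$sentiment_mode,
                              negation_window = config$negation_window)
  instances <- assign_factor_polarity(factor_mentions, labels)
  instances <- enrich_mentions(instances, messages)
  label_counts <- as.list(table(factor(labels$four_class,
                                       levels = c("positive", "neutral",
                                                  "bilateral", "negative"))))
  manifest <- list(config_hash = config_hash(config),
                   n_threads = nrow(threads),
                   n_messages_in = nrow(messages),
                   n_retained = nrow(retained),
                   n_hospital_mentions = nrow(mentions),
                   n_factor_mentions = nrow(factor_mentions),
                   label_counts = lapply(label_counts, as.integer),
                   n_instances = nrow(instances))
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_artifact(mentions, file.path(config$output_dir, "hospital_mentions.tsv"))
    write_tsv_artifact(factor_mentions, file.path(config$output_dir, "factor_mentions.tsv"))
    write_tsv_artifact(labels, file.path(config$output_dir, "labels.tsv"))
    write_tsv_artifact(instances, file.path(config$output_dir, "instances.tsv"))
    writeLines(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE)),
               file.path(config$output_dir, "manifest.json"))
  }
  list(mentions = mentions, retained = retained,
       factor_mentions = factor_mentions, labels = labels,
       instances = instances, manifest = manifest)
}
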