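# Evaluation against gold labels: precision, recall and F1 per region with a
# macro average (each region weighted equally), reported as percentages.

#' Precision and recall of a predicted item set
#'
#' `P = 100 * |pred & gold| / |pred|` and `R = 100 * |pred & gold| / |gold|`.
#' An empty prediction set scores precision 0 against nonempty gold (100 when
#' both are empty), and symmetrically for recall.
#'
#' @param predicted,gold vectors of comparable item keys (duplicates ignored).
#' @return named numeric vector `c(precision, recall)` in percent.
#' @export
precision_recall <- function(predicted, gold) {
  predicted <- unique(predicted)
  gold <- unique(gold)
  inter <- length(intersect(predicted, gold))
  p <- if (length(predicted) == 0L) {
    if (length(gold) == 0L) 100 else 0
  } else 100 * inter / length(predicted)
  r <- if (length(gold) == 0L) {
    if (length(predicted) == 0L) 100 else 0
  } else 100 * inter / length(gold)
  c(precision = p, recall = r)
}

#' F1 score from precision and recall percentages
#'
#' The harmonic mean `2 P R / (P + R)`, defined as 0 when `P + R = 0`.
#' Presentation rounding to integer percent should use [round_half_up()].
#'
#' @param precision,recall numeric vectors in percent (0-100).
#' @return F1 in percent.
#' @export
#' @examples
#' round_half_up(f1(68, 83))  # 75
f1 <- function(precision, recall) {
  ifelse(precision + recall == 0, 0, 2 * precision * recall / (precision + recall))
}

task_key_column <- function(task) {
  switch(task,
         hospital_name = "canonical_id",
         factor_detection = "factor",
         recommendation = "binary")
}

#' Evaluate predictions against gold labels, per region
#'
#' The match policy is task-specific and deliberately message-grained:
#' hospital-name extraction compares `(message_id, canonical_id)` pairs,
#' factor detection compares `(message_id, factor)` pairs, and recommendation
#' classification compares `(message_id, binary)` labels and reports
#' precision only. One row per gold region plus an `Average` row holding the
#' macro mean.
#'
#' @param predictions,gold tibbles with columns `message_id`, `region`, and
#'   the task's key column (`canonical_id`, `factor` or `binary`).
#' @param task one of `"hospital_name"`, `"factor_detection"`,
#'   `"recommendation"`.
#' @return an `hm_eval_report` tibble with columns `region`, `precision`,
#'   `recall`, `f1` (recall and F1 are `NA` for the recommendation task),
#'   unrounded; `print()` rounds half-up to integer percent.
#' @export
evaluate_run <- function(predictions, gold,
                         task = c("hospital_name", "factor_detection",
                                  "recommendation")) {
  task <- match.arg(task)
  key_col <- task_key_column(task)
  for (nm in c("message_id", "region", key_col)) {
    if (!nm %in% names(predictions) || !nm %in% names(gold)) {
      hm_abort(sprintf("evaluate_run: both tables need a '%s' column", nm),
               class = "hospmine_usage_error")
    }
  }
  gregions <- sort(unique(gold$region))
  extra <- setdiff(unique(predictions$region), gregions)
  if (length(extra)) {
    hm_abort(sprintf("predictions contain region(s) absent from gold: %s",
                     paste(extra, collapse = ", ")),
             class = "hospmine_validation_error")
  }
  keyed <- function(df) paste(df$message_id, df[[key_col]], sep = "\r")
  rows <- lapply(gregions, function(r) {
    pr <- precision_recall(keyed(predictions[predictions$region == r, ]),
                           keyed(gold[gold$region == r, ]))
    if (task == "recommendation") {
      tibble(region = r, precision = pr[["precision"]],
             recall = NA_real_, f1 = NA_real_)
    } else {
      tibble(region = r, precision = pr[["precision"]], recall = pr[["recall"]],
             f1 = f1(pr[["precision"]], pr[["recall"]]))
    }
  })
  per <- bind_rows(rows)
  avg <- tibble(region = "Average",
                precision = mean(per$precision),
                recall = if (task == "recommendation") NA_real_ else mean(per$recall),
                f1 = if (task == "recommendation") NA_real_ else mean(per$f1))
  out <- bind_rows(per, avg)
  attr(out, "task") <- task
  class(out) <- c("hm_eval_report", class(out))
  out
}

#' @export
print.hm_eval_report <- function(x, ...) {
  cat(sprintf("Evaluation report (%s), percentages rounded half-up:\n",
              attr(x, "task")))
  y <- as_tibble(x)
  y$precision <- round_half_up(y$precision)
  y$recall <- round_half_up(y$recall)
  y$f1 <- round_half_up(y$f1)
  print(y, ...)
  invisible(x)
}
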