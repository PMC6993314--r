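#' Score predicted PHI spans against gold annotations
#'
#' Primary granularity is token-level: every token is counted once, labeled
#' by the span covering it (or `"O"`). Per type, a token is a true positive
#' when predicted and gold types match; the `"ALL"` row is type-insensitive
#' (PHI vs not-PHI), matching the convention used for cross-guideline
#' comparisons, and `"ALL_STRICT"` is the type-sensitive aggregate. Exact
#' span-and-type entity matching is reported as a secondary block.
#'
#' Conventions: recall is `NA` (undefined) when there are no gold positives;
#' precision is 1 when there are no predictions (vacuous truth, which extreme
#' bias sweeps do produce); F1 is 0 when recall and precision are both 0.
#'
#' @param corpus a `deid_corpus` carrying the gold spans.
#' @param predictions named list, one entry per note keyed by `note_id`,
#'   each a span data.frame as returned by [predict_phi()]. A key absent
#'   from the corpus is an error; notes without an entry count as all-`"O"`.
#' @return an `eval_report`: list with data.frames `token` and `entity`
#'   (columns `label`, `tp`, `fp`, `fn`, `recall`, `precision`, `f1`).
#' @export
score_deid <- function(corpus, predictions) {
  ids <- vapply(corpus$notes, function(n) n$note_id, character(1))
  unknown <- setdiff(names(predictions), ids)
  if (length(unknown) > 0)
    stop("prediction refers to unknown note_id '", unknown[1], "'")
  types <- phi_types()
  k <- length(types)
  tok <- matrix(0L, k + 2L, 3L,
                dimnames = list(c(types, "ALL", "ALL_STRICT"),
                                c("tp", "fp", "fn")))
  ent <- matrix(0L, k + 1L, 3L,
                dimnames = list(c(types, "ALL"), c("tp", "fp", "fn")))
  for (n in corpus$notes) {
    tokens <- tokenize(n$text)
    pred <- predictions[[n$note_id]]
    if (is.null(pred)) pred <- empty_spans()
    gtag <- bio_type(token_bio_tags(tokens, n$spans, warn_straddle = FALSE))
    ptag <- bio_type(token_bio_tags(tokens, pred, warn_straddle = FALSE))
    for (ty in types) {
      tok[ty, "tp"] <- tok[ty, "tp"] + sum(!is.na(gtag) & !is.na(ptag) &
                                           gtag == ty & ptag == ty)
      tok[ty, "fp"] <- tok[ty, "fp"] + sum(!is.na(ptag) & ptag == ty &
                                           (is.na(gtag) | gtag != ty))
      tok[ty, "fn"] <- tok[ty, "fn"] + sum(!is.na(gtag) & gtag == ty &
                                           (is.na(ptag) | ptag != ty))
    }
    tok["ALL", "tp"] <- tok["ALL", "tp"] + sum(!is.na(gtag) & !is.na(ptag))
    tok["ALL", "fp"] <- tok["ALL", "fp"] + sum(!is.na(ptag) & is.na(gtag))
    tok["ALL", "fn"] <- tok["ALL", "fn"] + sum(!is.na(gtag) & is.na(ptag))
    gkey <- span_keys(n$spans); pkey <- span_keys(pred)
    for (ty in types) {
      g <- gkey[n$spans$type == ty]; p <- pkey[pred$type == ty]
      ent[ty, "tp"] <- ent[ty, "tp"] + sum(p %in% g)
      ent[ty, "fp"] <- ent[ty, "fp"] + sum(!(p %in% g))
      ent[ty, "fn"] <- ent[ty, "fn"] + sum(!(g %in% p))
    }
  }
  tok["ALL_STRICT", ] <- colSums(tok[types, , drop = FALSE])
  ent["ALL", ] <- colSums(ent[types, , drop = FALSE])
  structure(list(token = finish_metrics(tok), entity = finish_metrics(ent)),
            class = "eval_report")
}

span_keys <- function(spans) {
  if (nrow(spans) == 0L) return(character())
  paste(spans$start, spans$end, spans$type, sep = ":")
}

finish_metrics <- function(m) {
  tp <- m[, "tp"]; fp <- m[, "fp"]; fn <- m[, "fn"]
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 1)
  f1 <- ifelse(is.na(recall), NA_real_,
               ifelse(recall + precision > 0,
                      2 * recall * precision / (recall + precision), 0))
  data.frame(label = rownames(m), tp = tp, fp = fp, fn = fn,
             recall = recall, precision = precision, f1 = f1,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Token-level metrics:\n")
  print(x$token, digits = 4)
  invisible(x)
}

# convenience accessor: one token-level metric for one label row
report_metric <- function(report, label, metric = "f1") {
  report$token[report$token$label == label, metric]
}

#' Serialize an evaluation report
#'
#' Writes the recall/precision/F1 triplets as a tab-separated table, and
#' optionally the full report (token and entity blocks) as JSON.
#'
#' @param report an `eval_report` from [score_deid()].
#' @param path TSV file to write.
#' @param json_path optional JSON file.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path, json_path = NULL) {
  utils::write.table(report$token, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Recall at fixed precision (R@P)
#'
#' Sweeps the not-PHI emission bias over a grid, decoding the test corpus
#' once per grid point, and reports the highest token-level PHI recall among
#' operating points whose precision meets the cutoff `p` (default 0.85).
#' When no point qualifies the metric does not adjust: it returns the recall
#' at bias 0 and flags the cutoff as unmet. Increasing the bias makes the
#' decoder more conservative, trading recall for precision.
#'
#' @param model a trained `deid_tagger`.
#' @param test a non-empty `deid_corpus`.
#' @param table an [embedding_table()].
#' @param p precision cutoff in `[0, 1]`.
#' @param bias_grid ordered bias grid; the default 41 points cover -4..4 in
#'   steps of 0.2.
#' @return list with `recall`, `operating_point` (row of the sweep), `sweep`
#'   (data.frame `bias`, `recall`, `precision`) and `unmet`.
#' @export
recall_at_precision <- function(model, test, table, p = 0.85,
                                bias_grid = seq(-4, 4, by = 0.2)) {
  if (length(test) == 0L) stop("empty test corpus")
  stopifnot(!is.unsorted(bias_grid), p >= 0, p <= 1)
  lstm <- model$config$cell == "lstm"
  prepped <- Filter(Negate(is.null),
                    lapply(test$notes, prepare_note, table = table,
                           model = model))
  emis_list <- lapply(prepped, function(x)
    cpp_emissions(model$params, x, lstm))
  gold_phi <- lapply(prepped, function(x) x$labels > 0L)

  sweep <- data.frame(bias = bias_grid, recall = NA_real_,
                      precision = NA_real_)
  for (i in seq_along(bias_grid)) {
    tp <- fp <- fn <- 0L
    for (j in seq_along(emis_list)) {
      e <- emis_list[[j]]
      e[, 1L] <- e[, 1L] + bias_grid[i]
      pred <- as.integer(cpp_crf_viterbi(e, model$params$trans)$path) > 0L
      g <- gold_phi[[j]]
      tp <- tp + sum(pred & g)
      fp <- fp + sum(pred & !g)
      fn <- fn + sum(!pred & g)
    }
    sweep$recall[i] <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    sweep$precision[i] <- if (tp + fp > 0) tp / (tp + fp) else 1
  }
  sel <- select_operating_point(sweep, p)
  c(sel, list(sweep = sweep))
}

#' Choose the R@P operating point from a sweep
#'
#' Pure selection rule, usable on any `(bias, recall, precision)` table:
#' among points with `precision >= p` return the one with maximal recall;
#' if none qualifies, return the point at bias 0 (or nearest the sweep has
#' to 0) with `unmet = TRUE`.
#'
#' @param sweep data.frame with columns `bias`, `recall`, `precision`.
#' @param p precision cutoff.
#' @return list with `recall`, `operating_point`, `unmet`.
#' @export
select_operating_point <- function(sweep, p) {
  ok <- which(!is.na(sweep$recall) & sweep$precision >= p)
  if (length(ok) > 0) {
    best <- ok[which.max(sweep$recall[ok])]
    list(recall = sweep$recall[best], operating_point = sweep[best, ],
         unmet = FALSE)
  } else {
    at0 <- which.min(abs(sweep$bias))
    list(recall = sweep$recall[at0], operating_point = sweep[at0, ],
         unmet = TRUE)
  }
}

#' Token-level error listing
#'
#' Lists every token-level false negative (gold PHI missed or mistyped) and
#' false positive (predicted PHI that is not gold PHI of that type), each
#' with its note, offsets, type and a +/- 40 character context window.
#' Grouped counts agree with the type-sensitive token counts of
#' [score_deid()].
#'
#' @param corpus a `deid_corpus` with gold spans.
#' @param predictions named list of predicted span data.frames (see
#'   [score_deid()]).
#' @param context characters of context on each side.
#' @return list of data.frames `fn` and `fp` with columns `note_id`,
#'   `start`, `end`, `type`, `token`, `context`.
#' @export
error_report <- function(corpus, predictions, context = 40L) {
  fn <- fp <- list()
  for (n in corpus$notes) {
    tokens <- tokenize(n$text)
    pred <- predictions[[n$note_id]]
    if (is.null(pred)) pred <- empty_spans()
    gtag <- bio_type(token_bio_tags(tokens, n$spans, warn_straddle = FALSE))
    ptag <- bio_type(token_bio_tags(tokens, pred, warn_straddle = FALSE))
    mk <- function(i, type) data.frame(
      note_id = n$note_id, start = tokens$start[i], end = tokens$end[i],
      type = type, token = tokens$text[i],
      context = substring(n$text, pmax(1L, tokens$start[i] - context + 1L),
                          pmin(nchar(n$text), tokens$end[i] + context)),
      stringsAsFactors = FALSE)
    miss <- which(!is.na(gtag) & (is.na(ptag) | ptag != gtag))
    if (length(miss)) fn[[length(fn) + 1L]] <- mk(miss, gtag[miss])
    spur <- which(!is.na(ptag) & (is.na(gtag) | gtag != ptag))
    if (length(spur)) fp[[length(fp) + 1L]] <- mk(spur, ptag[spur])
  }
  empty <- data.frame(note_id = character(), start = integer(),
                      end = integer(), type = character(),
                      token = character(), context = character(),
                      stringsAsFactors = FALSE)
  list(fn = if (length(fn)) do.call(rbind, fn) else empty,
       fp = if (length(fp)) do.call(rbind, fp) else empty)
}

#' Predict spans for every note in a corpus
#'
#' Convenience wrapper producing the named prediction list consumed by
#' [score_deid()] and [error_report()].
#'
#' @param model a trained `deid_tagger`.
#' @param corpus a `deid_corpus`.
#' @param table an [embedding_table()].
#' @param not_phi_bias decode-time bias.
#' @return named list of span data.frames keyed by `note_id`.
#' @export
predict_corpus <- function(model, corpus, table,
                           not_phi_bias = model$not_phi_bias) {
  preds <- lapply(corpus$notes, function(n)
    predict_phi(model, n$text, table, not_phi_bias = not_phi_bias))
  names(preds) <- vapply(corpus$notes, function(n) n$note_id, character(1))
  preds
}
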