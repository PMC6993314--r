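mk_note <- function(id, text, spans = empty_spans(), patient = "p1")
  annotated_note(id, text, spans, patient_id = patient)

test_that("token-level counts follow the metric definitions", {
  # 10 gold PHI tokens; predictions recover 8 and add 2 spurious ones
  text <- paste(sprintf("tok%02d", 1:20), collapse = " ")
  tk <- tokenize(text)
  gold <- do.call(rbind, lapply(1:10, function(i)
    phi_span(tk$start[i], tk$end[i], "NAME")))
  pred <- do.call(rbind, lapply(c(1:8, 15, 16), function(i)
    phi_span(tk$start[i], tk$end[i], "NAME")))
  corp <- deid_corpus(list(mk_note("n1", text, gold)))
  rep <- score_deid(corp, list(n1 = pred))
  all_row <- rep$token[rep$token$label == "ALL", ]
  expect_equal(all_row$recall, 0.8)
  expect_equal(all_row$precision, 0.8)
  expect_equal(all_row$tp + all_row$fn, 10)
  # perfect prediction
  perfect <- score_deid(corp, list(n1 = gold))
  p_row <- perfect$token[perfect$token$label == "ALL", ]
  expect_equal(c(p_row$recall, p_row$precision, p_row$f1), c(1, 1, 1))
  # no predictions: recall 0, precision 1 by convention, F1 0
  none <- score_deid(corp, list(n1 = empty_spans()))
  n_row <- none$token[none$token$label == "ALL", ]
  expect_equal(c(n_row$recall, n_row$precision, n_row$f1), c(0, 1, 0))
  # unknown note_id is a contract violation
  expect_error(score_deid(corp, list(ghost = pred)), "unknown note_id")
})

test_that("scores are invariant under note reordering and split by type", {
  corp <- tiny_corpus(10, seed = 33)
  preds <- lapply(corp$notes, function(n) n$spans[-1, , drop = FALSE])
  names(preds) <- vapply(corp$notes, function(n) n$note_id, character(1))
  r1 <- score_deid(corp, preds)
  shuf <- deid_corpus(corp$notes[rev(seq_along(corp$notes))])
  r2 <- score_deid(shuf, preds)
  expect_equal(r1$token, r2$token)
  # type-sensitive aggregate equals the per-type sums
  types <- phi_types()
  strict <- r1$token[r1$token$label == "ALL_STRICT", ]
  expect_equal(strict$tp, sum(r1$token$tp[r1$token$label %in% types]))
  # gold token totals are preserved per type
  for (ty in types) {
    row <- r1$token[r1$token$label == ty, ]
    gold_tokens <- sum(vapply(corp$notes, function(n) {
      tags <- deidtag:::token_bio_tags(tokenize(n$text), n$spans,
                                       warn_straddle = FALSE)
      sum(deidtag:::bio_type(tags) %in% ty)
    }, numeric(1)))
    expect_equal(row$tp + row$fn, gold_tokens)
  }
})

test_that("operating-point selection implements the R@P rule", {
  sweep <- data.frame(bias = c(-1, 0, 1),
                      recall = c(0.99, 0.95, 0.90),
                      precision = c(0.60, 0.86, 0.92))
  sel <- select_operating_point(sweep, 0.85)
  expect_equal(sel$recall, 0.95)
  expect_false(sel$unmet)
  # a vacuous cutoff returns the sweep maximum
  expect_equal(select_operating_point(sweep, 0)$recall, 0.99)
  # when nothing qualifies, fall back to bias 0 and flag it
  strict <- select_operating_point(sweep, 0.99)
  expect_true(strict$unmet)
  expect_equal(strict$recall, 0.95)
  # R@P is non-increasing in p wherever the cutoff is met (the "not
  # adjusting" fallback re-raises recall once nothing qualifies)
  ps <- seq(0, 1, by = 0.05)
  sels <- lapply(ps, select_operating_point, sweep = sweep)
  rs <- vapply(sels, `[[`, numeric(1), "recall")
  met <- !vapply(sels, `[[`, logical(1), "unmet")
  expect_true(all(diff(rs[met]) <= 1e-12))
  expect_true(all(vapply(sels[!met], `[[`, numeric(1), "recall") == 0.95))
})

test_that("error listings agree with the token-level confusion counts", {
  corp <- tiny_corpus(8, seed = 34)
  preds <- lapply(corp$notes, function(n) {
    s <- n$spans
    if (nrow(s) > 1) s <- s[-2, , drop = FALSE]  # drop one span per note
    s
  })
  names(preds) <- vapply(corp$notes, function(n) n$note_id, character(1))
  rep <- score_deid(corp, preds)
  errs <- error_report(corp, preds)
  types <- phi_types()
  for (ty in types) {
    row <- rep$token[rep$token$label == ty, ]
    expect_equal(sum(errs$fn$type == ty), row$fn)
    expect_equal(sum(errs$fp$type == ty), row$fp)
  }
  expect_true(all(nchar(errs$fn$context) <= 40 * 2 +
                    max(nchar(errs$fn$token), 0)))
  # perfect predictions produce an empty listing
  full <- lapply(corp$notes, function(n) n$spans)
  names(full) <- names(preds)
  e0 <- error_report(corp, full)
  expect_equal(nrow(e0$fn), 0L)
  expect_equal(nrow(e0$fp), 0L)
})

test_that("report serialization writes the metric triplets", {
  corp <- tiny_corpus(4, seed = 35)
  preds <- lapply(corp$notes, function(n) n$spans)
  names(preds) <- vapply(corp$notes, function(n) n$note_id, character(1))
  rep <- score_deid(corp, preds)
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_eval_report(rep, tsv, json_path = js)
  tab <- utils::read.delim(tsv)
  expect_true(all(c("label", "recall", "precision", "f1") %in% names(tab)))
  parsed <- jsonlite::fromJSON(js)
  expect_true(all(parsed$token$f1[parsed$token$label == "ALL"] == 1))
})
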