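#' Deployment-scenario configuration
#'
#' Describes one of the customization scenarios a deploying organization
#' faces: `full_custom` (train and test on A), `off_the_shelf` (train on A,
#' test on B), the three small-labeled-sample regimes `only_b`, `a_then_b`
#' and `a_mix_b` (n labeled target-PHI instances from B), and
#' `custom_embedding` (train on A with an embedding built from B's unlabeled
#' text).
#'
#' @param mode scenario mode.
#' @param corpus_a,corpus_b source and target corpora (`deid_corpus`); modes
#'   touching B require `corpus_b`.
#' @param n_labeled number of labeled target-PHI instances drawn from B's
#'   training partition (whole notes are selected; see
#'   [select_notes_by_phi_count()]).
#' @param phi_type_for_counting PHI category in which `n_labeled` is counted
#'   (default NAME, the category labeled consistently across guidelines).
#' @param embedding optional [embedding_table()]; when `NULL`, a skip-gram
#'   table is trained on the scenario's available unlabeled text (B's
#'   training text for `custom_embedding`, otherwise A's).
#' @param model_a optional pre-trained source model, reused instead of
#'   retraining for `off_the_shelf` and `a_then_b`.
#' @param train_fraction patient-level train share of each corpus split.
#' @param rp_p precision cutoff for the recall-at-precision metric.
#' @param seed integer seed.
#' @return a `scenario_config`.
#' @export
scenario_config <- function(mode = c("full_custom", "off_the_shelf", "only_b",
                                     "a_then_b", "a_mix_b",
                                     "custom_embedding"),
                            corpus_a = NULL, corpus_b = NULL,
                            n_labeled = 0L, phi_type_for_counting = "NAME",
                            embedding = NULL, model_a = NULL,
                            train_fraction = 0.75, rp_p = 0.85, seed = 1L) {
  mode <- match.arg(mode)
  needs_b <- mode != "full_custom"
  if (needs_b && is.null(corpus_b)) stop("mode '", mode, "' requires corpus_b")
  if (mode %in% c("full_custom", "off_the_shelf", "a_then_b", "a_mix_b",
                  "custom_embedding") && is.null(corpus_a))
    stop("mode '", mode, "' requires corpus_a")
  if (mode %in% c("only_b", "a_mix_b") && n_labeled <= 0L)
    stop("mode '", mode, "' requires n_labeled > 0")
  stopifnot(n_labeled >= 0, phi_type_for_counting %in% phi_types())
  structure(list(mode = mode, corpus_a = corpus_a, corpus_b = corpus_b,
                 n_labeled = as.integer(n_labeled),
                 phi_type_for_counting = phi_type_for_counting,
                 embedding = embedding, model_a = model_a,
                 train_fraction = train_fraction, rp_p = rp_p,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Select notes until a target PHI-instance count is reached
#'
#' Draws whole notes in a seeded random order until the cumulative count of
#' `phi_type` instances reaches `n` (annotation happens note-wise, so the
#' budget is counted in instances but spent in notes). The selected subset
#' therefore contains at least `n` instances, overshooting by less than the
#' last note's count.
#'
#' @param corpus a `deid_corpus`.
#' @param phi_type PHI category counted toward `n`.
#' @param n target instance count; `n = 0` selects nothing.
#' @param seed integer seed.
#' @return a `deid_corpus` subset.
#' @export
select_notes_by_phi_count <- function(corpus, phi_type = "NAME", n, seed = 1L) {
  stopifnot(n >= 0)
  if (n == 0L) return(deid_corpus(list(), name = corpus$name))
  counts <- vapply(corpus$notes, function(x) sum(x$spans$type == phi_type),
                   integer(1))
  if (sum(counts) < n)
    stop("corpus has only ", sum(counts), " ", phi_type,
         " instances; ", n, " requested")
  ord <- with_seed(seed, sample(length(corpus)))
  cum <- cumsum(counts[ord])
  k <- which(cum >= n)[1]
  deid_corpus(corpus$notes[sort(ord[seq_len(k)])],
              name = paste0(corpus$name, "-n", n))
}

#' Run one deployment scenario end to end
#'
#' Splits the corpora by patient, trains (or adapts) the tagger according to
#' the scenario mode, and evaluates on the appropriate held-out test
#' partition: A's test split for `full_custom`, B's for everything else.
#' For `a_mix_b`, every minibatch is drawn half from A and half from the
#' selected B subset, the smaller side resampled with replacement. Fully
#' seeded: identical configs give identical results.
#'
#' @param cfg a [scenario_config()].
#' @param mcfg a [model_config()].
#' @param tcfg a [train_config()]; its seed is overridden by `cfg$seed`.
#' @param verbose print training progress.
#' @return a `scenario_result`: list with `mode`, `report` (an
#'   `eval_report`), `rp` (recall-at-precision result), `model`, `table`,
#'   `test` (the evaluation corpus) and `n_labeled`.
#' @export
run_scenario <- function(cfg, mcfg = model_config(), tcfg = train_config(),
                         verbose = FALSE) {
  tcfg$seed <- cfg$seed
  split_a <- if (!is.null(cfg$corpus_a))
    split_by_patient(cfg$corpus_a, cfg$train_fraction, seed = cfg$seed)
  split_b <- if (!is.null(cfg$corpus_b))
    split_by_patient(cfg$corpus_b, cfg$train_fraction, seed = cfg$seed)

  table <- cfg$embedding
  if (is.null(table)) {
    emb_source <- if (cfg$mode == "custom_embedding") split_b$train
                  else if (!is.null(split_a)) split_a$train
                  else split_b$train
    table <- train_skipgram(emb_source, dim = mcfg$token_embedding_dim,
                            seed = cfg$seed)
  }

  subset_b <- NULL
  if (cfg$mode %in% c("only_b", "a_then_b", "a_mix_b") && cfg$n_labeled > 0L)
    subset_b <- select_notes_by_phi_count(split_b$train,
                                          cfg$phi_type_for_counting,
                                          cfg$n_labeled, seed = cfg$seed)

  train_a <- function() {
    if (!is.null(cfg$model_a)) cfg$model_a
    else train_tagger(split_a$train, table, mcfg, tcfg, verbose = verbose)
  }
  model <- switch(cfg$mode,
    full_custom = train_a(),
    off_the_shelf = train_a(),
    custom_embedding = train_tagger(split_a$train, table, mcfg, tcfg,
                                    verbose = verbose),
    only_b = train_tagger(subset_b, table, mcfg, tcfg, verbose = verbose),
    a_then_b = {
      m <- train_a()
      if (is.null(subset_b)) m                    # n = 0: off the shelf
      else fine_tune(m, subset_b, table, tcfg, verbose = verbose)
    },
    a_mix_b = train_tagger(split_a$train, table, mcfg, tcfg,
                           mix_with = subset_b, verbose = verbose))

  test <- if (cfg$mode == "full_custom") split_a$test else split_b$test
  preds <- predict_corpus(model, test, table)
  report <- score_deid(test, preds)
  rp <- recall_at_precision(model, test, table, p = cfg$rp_p)
  structure(list(mode = cfg$mode, n_labeled = cfg$n_labeled,
                 seed = cfg$seed, report = report, rp = rp, model = model,
                 table = table, test = test, predictions = preds),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  all_row <- x$report$token[x$report$token$label == "ALL", ]
  cat(sprintf(
    "<scenario '%s' (n=%d): PHI recall %.3f, precision %.3f, F1 %.3f; R@P %.3f%s>\n",
    x$mode, x$n_labeled, all_row$recall, all_row$precision, all_row$f1,
    x$rp$recall, if (x$rp$unmet) " (cutoff unmet)" else ""))
  invisible(x)
}

#' Learning curve over labeled-sample budgets
#'
#' Runs the partial-customization strategies for every budget in `ns` and
#' every replicate, with replicate seeds derived as `seed + replicate - 1`.
#' The source model is trained once per replicate and shared by
#' `off_the_shelf`-equivalent points (`a_then_b` at n = 0) and `a_then_b`
#' fine-tuning. Emits one tidy row per (strategy, n, replicate).
#'
#' @param corpus_a,corpus_b source and target corpora.
#' @param ns ascending integer vector of labeled-instance budgets.
#' @param strategies subset of `c("only_b", "a_then_b", "a_mix_b")`.
#' @param replicates number of replicates.
#' @param mcfg,tcfg model and training configuration.
#' @param phi_type PHI category in which budgets are counted.
#' @param seed base seed.
#' @param rp_p precision cutoff passed through to the scenario runs.
#' @return data.frame with columns `strategy`, `n`, `replicate`, `recall`,
#'   `precision`, `f1`, `rp_recall` (token-level, all PHI types).
#' @export
learning_curve <- function(corpus_a, corpus_b, ns,
                           strategies = c("only_b", "a_then_b", "a_mix_b"),
                           replicates = 1L, mcfg = model_config(),
                           tcfg = train_config(), phi_type = "NAME",
                           seed = 1L, rp_p = 0.85) {
  stopifnot(!is.unsorted(ns), all(strategies %in%
                                  c("only_b", "a_then_b", "a_mix_b")))
  rows <- list()
  for (r in seq_len(replicates)) {
    seed_r <- seed + r - 1L
    base_cfg <- scenario_config("off_the_shelf", corpus_a, corpus_b,
                                seed = seed_r, rp_p = rp_p)
    base <- run_scenario(base_cfg, mcfg, tcfg)
    for (strat in strategies) {
      for (n in ns) {
        res <- if (n == 0L) {
          if (strat %in% c("a_then_b", "a_mix_b")) base else NULL
        } else {
          cfg <- scenario_config(strat, corpus_a, corpus_b, n_labeled = n,
                                 phi_type_for_counting = phi_type,
                                 embedding = base$table,
                                 model_a = base$model, seed = seed_r,
                                 rp_p = rp_p)
          run_scenario(cfg, mcfg, tcfg)
        }
        all_row <- if (is.null(res)) data.frame(recall = NA, precision = NA,
                                                f1 = NA)
                   else res$report$token[res$report$token$label == "ALL", ]
        rows[[length(rows) + 1L]] <- data.frame(
          strategy = strat, n = n, replicate = r,
          recall = all_row$recall, precision = all_row$precision,
          f1 = all_row$f1,
          rp_recall = if (is.null(res)) NA_real_ else res$rp$recall,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Recall on a chosen subset of gold PHI tokens
#'
#' Fraction of gold tokens of the given type whose surface is in `surfaces`
#' that the predictions mark as PHI (any type). Used to quantify the "local
#' jargon" failure mode: recall of an off-the-shelf model on target-only
#' jargon LOCATION tokens.
#'
#' @param corpus a `deid_corpus` with gold spans.
#' @param predictions named prediction list (see [score_deid()]).
#' @param surfaces character vector of token surfaces to restrict to, or
#'   `NULL` for all tokens of the type.
#' @param type gold PHI category to restrict to.
#' @return list with `n` (gold tokens in the subset) and `recall`.
#' @export
subset_token_recall <- function(corpus, predictions, surfaces = NULL,
                                type = "LOCATION") {
  n_tok <- 0L; hit <- 0L
  for (note in corpus$notes) {
    tokens <- tokenize(note$text)
    gtag <- bio_type(token_bio_tags(tokens, note$spans, warn_straddle = FALSE))
    pred <- predictions[[note$note_id]]
    if (is.null(pred)) pred <- empty_spans()
    ptag <- bio_type(token_bio_tags(tokens, pred, warn_straddle = FALSE))
    sel <- !is.na(gtag) & gtag == type
    if (!is.null(surfaces)) sel <- sel & tokens$text %in% surfaces
    n_tok <- n_tok + sum(sel)
    hit <- hit + sum(sel & !is.na(ptag))
  }
  list(n = n_tok, recall = if (n_tok > 0) hit / n_tok else NA_real_)
}
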