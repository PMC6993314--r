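test_that("analytic gradients match finite differences", {
  set.seed(8)
  mcfg <- model_config(token_embedding_dim = 4, char_input_dim = 3,
                       char_hidden = 3, char_embedding_dim = 3,
                       token_hidden = 4, dropout = 0)
  note <- list(emb = matrix(rnorm(4 * 3), 4, 3),
               chars = list(c(1L, 2L), 0L, c(2L, 0L, 1L)),
               feats = matrix(runif(6 * 3), 6, 3),
               labels = c(0L, 1L, 0L))
  for (cell in c("lstm", "rnn")) {
    model <- init_tagger(model_config(token_embedding_dim = 4,
                                      char_input_dim = 3, char_hidden = 3,
                                      char_embedding_dim = 3,
                                      token_hidden = 4, cell = cell),
                         c("<unk>", "a", "b"), seed = 4)
    lstm <- cell == "lstm"
    gr <- deidtag:::cpp_batch_grad(model$params, list(note), lstm, 0, FALSE)
    for (nm in c("Wt_f", "Uc_b", "C_emb", "Pc", "trans", "Wo")) {
      i <- sample(length(model$params[[nm]]), 1)
      eps <- 1e-5
      up <- model$params; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- model$params; dn[[nm]][i] <- dn[[nm]][i] - eps
      fd <- (deidtag:::cpp_note_loss(up, note, lstm) -
             deidtag:::cpp_note_loss(dn, note, lstm)) / (2 * eps)
      expect_equal(gr$grads[[nm]][i], fd, tolerance = 1e-6)
    }
  }
})

test_that("training reduces the loss and is seed-deterministic", {
  corp <- tiny_corpus(40, seed = 13)
  tab <- tiny_table(corp)
  m1 <- train_tagger(corp, tab, small_mcfg(), small_tcfg(max_epochs = 3,
                                                         seed = 5))
  expect_lt(m1$history$loss[3], m1$history$loss[1])
  m2 <- train_tagger(corp, tab, small_mcfg(), small_tcfg(max_epochs = 3,
                                                         seed = 5))
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  # a corpus without PHI spans cannot train a tagger
  blank <- deid_corpus(list(annotated_note("b1", "nothing to find here",
                                           patient_id = "p1"),
                            annotated_note("b2", "still nothing",
                                           patient_id = "p2")))
  expect_error(train_tagger(blank, tab, small_mcfg(), small_tcfg()),
               "no PHI spans")
})

test_that("fine-tuning with no epoch budget is the identity", {
  corp <- tiny_corpus(30, seed = 14)
  tab <- tiny_table(corp)
  model <- train_tagger(corp, tab, small_mcfg(), small_tcfg(max_epochs = 2))
  same <- fine_tune(model, corp, tab, small_tcfg(max_epochs = 0))
  expect_identical(same$params, model$params)
})

test_that("decoded BIO tags convert to character spans with I-repair", {
  tk <- tokenize("John London complains")
  spans <- deidtag:::bio_to_spans(c("B-NAME", "I-NAME", "O"), tk)
  expect_equal(nrow(spans), 1L)
  expect_equal(c(spans$start, spans$end), c(0L, 11L))
  expect_equal(spans$type, "NAME")
  # an ill-formed leading I-X opens a span as if it were B-X
  spans2 <- deidtag:::bio_to_spans(c("I-DATE", "I-DATE", "O"), tk)
  expect_equal(spans2$type, "DATE")
  expect_equal(c(spans2$start, spans2$end), c(0L, 11L))
  # type change without B starts a new span
  spans3 <- deidtag:::bio_to_spans(c("B-NAME", "I-DATE", "O"), tk)
  expect_equal(spans3$type, c("NAME", "DATE"))
})

test_that("prediction handles empty notes and recovers planted spans", {
  corp <- tiny_corpus(60, seed = 15)
  tab <- tiny_table(corp)
  model <- train_tagger(corp, tab, small_mcfg(),
                        small_tcfg(max_epochs = 8, seed = 2))
  expect_equal(nrow(predict_phi(model, "", tab)), 0L)
  note <- corp$notes[[3]]
  pred <- predict_phi(model, note$text, tab)
  expect_true(nrow(pred) > 0)
  expect_equal(pred$text, substring(note$text, pred$start + 1, pred$end))
  # checkpoints round-trip through disk
  path <- tempfile(fileext = ".rds")
  save_tagger(model, path)
  back <- load_tagger(path)
  expect_identical(back$params, model$params)
  expect_identical(predict_phi(back, note$text, tab), pred)
})

test_that("raising the not-PHI bias never increases predicted PHI tokens", {
  corp <- tiny_corpus(50, seed = 16)
  tab <- tiny_table(corp)
  model <- train_tagger(corp, tab, small_mcfg(),
                        small_tcfg(max_epochs = 6, seed = 3))
  test <- tiny_corpus(15, seed = 99)
  counts <- vapply(seq(-3, 3, by = 1), function(b) {
    sum(vapply(test$notes, function(n) {
      tags <- deidtag:::predict_tags(model, tokenize(n$text), tab,
                                     not_phi_bias = b)
      sum(tags != "O")
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})
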